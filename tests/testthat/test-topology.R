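test_that("Newick parsing keeps topology and discards lengths, labels, comments", {
  t1 <- parse_newick("((A,B),(C,D));")
  expect_equal(n_nodes(t1), 7L)
  expect_equal(t1$n_leaf, 4L)
  expect_equal(t1$parent[1], 0L)
  t2 <- parse_newick("((A:1.2,B:0.3)n1:5,(C,D));")
  expect_true(t1 == t2)
  t3 <- parse_newick("((A[comment],B),(C,D))[whole tree];")
  expect_true(t1 == t3)
})

test_that("malformed or duplicated input is rejected with informative errors", {
  expect_error(parse_newick("((A,B),(A,C));"), "duplicate")
  expect_error(parse_newick("((A,B),(C,D);"), "character")
  expect_error(parse_newick("(A,B)),C;"), "character")
})

test_that("parse -> serialize -> parse round-trips random topologies", {
  for (s in 1:20) {
    t <- simulate_tree(sample(4:15, 1), seed = s)
    t2 <- parse_newick(serialize_newick(t))
    expect_true(t == t2)
  }
})

test_that("bipartitions enumerates exactly the non-trivial unrooted splits", {
  expect_equal(bipartitions(parse_newick("((A,B),(C,D));")), "A|B")
  expect_equal(bipartitions(parse_newick("(A,B,C);")), character(0))
  expect_equal(bipartitions(parse_newick("((((A,B),C),D),E);")),
               sort(c("A|B", "A|B|C")))
  # both rootings of the same unrooted tree give the same splits
  expect_equal(bipartitions(parse_newick("(((A,B),C),(D,E));")),
               bipartitions(parse_newick("((D,E),(C,(A,B)));")))
})

test_that("Robinson-Foulds matches hand values and errors on leaf mismatch", {
  t1 <- parse_newick("((A,B),(C,D));")
  t2 <- parse_newick("((A,C),(B,D));")
  expect_equal(robinson_foulds(t1, t1), 0L)
  expect_equal(robinson_foulds(t1, t2), 2L)
  expect_equal(robinson_foulds(t1, t2), robinson_foulds(t2, t1))
  expect_error(robinson_foulds(t1, parse_newick("((A,B),(C,E));")), "E")
})

test_that("Robinson-Foulds is a metric within the binary-tree bound", {
  for (s in 1:15) {
    n <- sample(5:10, 1)
    a <- simulate_tree(n, seed = 3 * s)
    b <- simulate_tree(n, seed = 3 * s + 1)
    c_ <- simulate_tree(n, seed = 3 * s + 2)
    dab <- robinson_foulds(a, b)
    dbc <- robinson_foulds(b, c_)
    dac <- robinson_foulds(a, c_)
    expect_gte(dab, 0)
    expect_equal(robinson_foulds(a, b), robinson_foulds(b, a))
    expect_lte(dac, dab + dbc)   # triangle inequality
    expect_lte(dab, 2 * (n - 3)) # binary-tree upper bound
    expect_identical(robinson_foulds(a, a), 0L)
  }
})

test_that("supertree reproduces agreeing inputs and merges disjoint ones", {
  t <- parse_newick("((A,B),(C,D));")
  expect_true(build_supertree(list(t, t)) == t)
  st <- build_supertree(list(parse_newick("(A,B);"), parse_newick("(C,D);")))
  dl <- serialize_newick(st)
  expect_true(dl %in% c("((A,B),(C,D));", "((C,D),(A,B));"))
  st2 <- build_supertree(list(parse_newick("((A,B),C);"),
                              parse_newick("((A,B),D);")))
  expect_true("A|B" %in% bipartitions(st2))
  expect_setequal(leaf_labels(st2), c("A", "B", "C", "D"))
})

test_that("supertree is no farther from the inputs than any single input", {
  trees <- list(parse_newick("(((A,B),C),(D,E));"),
                parse_newick("(((A,B),D),(C,E));"),
                parse_newick("(((A,B),C),(D,E));"))
  st <- build_supertree(trees)
  total <- function(cand) sum(vapply(trees, robinson_foulds, 0L, t1 = cand))
  best_single <- min(vapply(trees, total, 0L))
  expect_lte(total(st), best_single)
})

test_that("contradictory inputs yield a partially unresolved tree, not an error", {
  st <- build_supertree(list(parse_newick("((A,B),(C,D));"),
                             parse_newick("((A,C),(B,D));"),
                             parse_newick("((A,D),(B,C));")))
  expect_s3_class(st, "topology")
  expect_setequal(leaf_labels(st), c("A", "B", "C", "D"))
})

test_that("prune_leaves drops taxa, suppresses unary nodes and maps ids", {
  t <- parse_newick("((A,B),(C,D));")
  same <- prune_leaves(t, character(0))
  expect_true(same$topology == t)
  expect_equal(same$map, 1:7)
  pr <- prune_leaves(t, "D")
  expect_equal(serialize_newick(pr$topology), "((A,B),C);")
  expect_true(is.na(pr$map[5]))           # suppressed unary node
  expect_error(prune_leaves(t, c("A", "B", "C", "D")), "all leaves")
  expect_error(prune_leaves(t, "Z"), "unknown")
})

test_that("pruning commutes with bipartition restriction on random trees", {
  for (s in 1:12) {
    n <- sample(6:14, 1)
    t <- simulate_tree(n, seed = 100 + s)
    labs <- leaf_labels(t)
    set.seed(s)
    drop <- sample(labs, sample(1:(n - 4), 1))
    pr <- prune_leaves(t, drop)
    expect_equal(bipartitions(pr$topology),
                 restrict_splits(bipartitions(t), setdiff(labs, drop)))
  }
})

test_that("RF distance equals the independent phangorn oracle on random pairs", {
  skip_if_not_installed("phangorn")
  for (s in 1:25) {
    n <- sample(5:12, 1)
    a <- simulate_tree(n, seed = 500 + 2 * s)
    b <- simulate_tree(n, seed = 501 + 2 * s)
    pa <- ape::unroot(ape::read.tree(text = serialize_newick(a)))
    pb <- ape::unroot(ape::read.tree(text = serialize_newick(b)))
    expect_equal(robinson_foulds(a, b),
                 as.integer(phangorn::RF.dist(pa, pb)))
  }
})

test_that("nearest surviving ancestor walks past suppressed nodes", {
  t <- parse_newick("(((A,B),C),D);")
  pr <- prune_leaves(t, "B")
  leafB <- which(t$label == "B")
  anc <- nearest_surviving_ancestor(t, leafB, pr$map)
  # B's parent (the AB cherry) was suppressed; grandparent survives
  expect_false(is.na(pr$map[2]))
  expect_equal(anc, pr$map[2])
})
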