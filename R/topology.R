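#' Rooted tree topologies
#'
#' A `topology` is a rooted, branch-length-free tree over labelled leaves.
#' Nodes are numbered in preorder: the root has id 1 and every node's parent
#' has a smaller id than the node itself. Leaves carry unique non-empty
#' labels; internal nodes carry the empty string. Polytomies are allowed.
#'
#' @param parent integer vector; `parent[i]` is the id of node `i`'s parent,
#'   with `parent[1] = 0` marking the root.
#' @param label character vector of the same length; taxon names for leaves,
#'   `""` for internal nodes.
#' @return An object of class `topology` with fields `parent`, `label`,
#'   `is_leaf` and `n_leaf`.
#' @examples
#' # the four-leaf balanced tree ((A,B),(C,D))
#' topology(parent = c(0L, 1L, 2L, 2L, 1L, 5L, 5L),
#'          label  = c("", "", "A", "B", "", "C", "D"))
#' @export
topology <- function(parent, label) {
  parent <- as.integer(parent)
  label <- as.character(label)
  n <- length(parent)
  stopifnot(length(label) == n, n >= 1L)
  if (parent[1] != 0L || any(parent[-1] <= 0L))
    stop("node 1 must be the unique root (parent 0); all other parents positive")
  if (n > 1L && any(parent[-1] >= seq_len(n)[-1]))
    stop("node ids must be in preorder: parent id < child id")
  is_leaf <- !(seq_len(n) %in% parent)
  if (any(label[is_leaf] == "") || anyNA(label[is_leaf]))
    stop("every leaf must have a non-empty label")
  if (anyDuplicated(label[is_leaf]))
    stop("duplicate leaf labels: ",
         paste(unique(label[is_leaf][duplicated(label[is_leaf])]), collapse = ", "))
  label[!is_leaf] <- ""
  structure(
    list(parent = parent, label = label, is_leaf = is_leaf,
         n_leaf = sum(is_leaf)),
    class = "topology"
  )
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("topology: %d leaves, %d internal nodes\n",
              x$n_leaf, n_nodes(x) - x$n_leaf))
  cat(" ", serialize_newick(x), "\n")
  invisible(x)
}

#' Number of nodes in a topology
#' @param t a `topology`
#' @return integer count of all nodes (leaves + internal)
#' @export
n_nodes <- function(t) length(t$parent)

#' Leaf labels of a topology, in node-id order
#' @param t a `topology`
#' @return character vector of taxon names
#' @export
leaf_labels <- function(t) t$label[t$is_leaf]

# children[[i]]: integer ids of node i's children (possibly empty)
topo_children <- function(t) {
  n <- n_nodes(t)
  ch <- vector("list", n)
  for (i in seq_len(n)[-1]) ch[[t$parent[i]]] <- c(ch[[t$parent[i]]], i)
  ch
}

# leaf labels descending from each node, as a list of character vectors
descendant_leaves <- function(t) {
  n <- n_nodes(t)
  out <- vector("list", n)
  for (i in rev(seq_len(n))) {
    if (t$is_leaf[i]) out[[i]] <- t$label[i]
    if (i > 1L) out[[t$parent[i]]] <- c(out[[t$parent[i]]], out[[i]])
  }
  out
}

#' @export
`==.topology` <- function(e1, e2) {
  identical(e1$parent, e2$parent) && identical(e1$label, e2$label)
}

#' Parse a Newick string into a topology
#'
#' Branch lengths, internal node labels and square-bracket comments are
#' accepted in the input and discarded; only the rooted topology and leaf
#' labels are kept. Parsing of the Newick grammar itself is delegated to
#' [ape::read.tree()].
#'
#' @param text a single Newick string (terminating `;` optional)
#' @return a [topology()]
#' @examples
#' parse_newick("((A:1.2,B:0.3)n1:5,(C,D));")
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  txt <- gsub("\\[[^]]*\\]", "", text)  # strip comments
  depth <- 0L
  chars <- strsplit(txt, "")[[1]]
  for (k in seq_along(chars)) {
    if (chars[k] == "(") depth <- depth + 1L
    if (chars[k] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop(sprintf("malformed Newick: unmatched ')' at character %d", k))
    }
  }
  if (depth != 0L)
    stop(sprintf("malformed Newick: %d unclosed '(' (string ends at character %d)",
                 depth, length(chars)))
  if (!grepl(";\\s*$", txt)) txt <- paste0(txt, ";")
  ph <- tryCatch(ape::read.tree(text = txt),
                 error = function(e) stop("malformed Newick: ", conditionMessage(e)))
  if (is.null(ph)) stop("malformed Newick: not a parsable tree")
  if (anyDuplicated(ph$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(ph$tip.label[duplicated(ph$tip.label)]), collapse = ", "))
  from_phylo(ph)
}

# ape::phylo -> topology (preorder renumbering, branch lengths dropped)
from_phylo <- function(ph) {
  ntip <- length(ph$tip.label)
  if (ntip == 1L && is.null(ph$edge)) return(topology(0L, ph$tip.label))
  edge <- ph$edge
  nmax <- max(edge)
  kids <- vector("list", nmax)
  for (r in seq_len(nrow(edge))) {
    kids[[edge[r, 1]]] <- c(kids[[edge[r, 1]]], edge[r, 2])
  }
  root <- ntip + 1L
  # iterative preorder DFS keeping ape's child order
  new_id <- integer(nmax)
  parent <- integer(0)
  label <- character(0)
  stack <- list(c(root, 0L))
  cnt <- 0L
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- top[1]; par_new <- top[2]
    cnt <- cnt + 1L
    new_id[node] <- cnt
    parent[cnt] <- par_new
    label[cnt] <- if (node <= ntip) ph$tip.label[node] else ""
    ch <- kids[[node]]
    if (length(ch)) {
      for (c_ in rev(ch)) stack[[length(stack) + 1L]] <- c(c_, cnt)
    }
  }
  topology(parent, label)
}

# topology -> ape::phylo (requires >= 2 leaves)
to_phylo <- function(t) {
  stopifnot(t$n_leaf >= 2L)
  ape::read.tree(text = serialize_newick(t))
}

#' Serialize a topology to Newick
#'
#' @param t a [topology()]
#' @return a Newick string ending in `;`, without branch lengths
#' @export
serialize_newick <- function(t) {
  ch <- topo_children(t)
  rec <- function(i) {
    if (t$is_leaf[i]) return(t$label[i])
    paste0("(", paste(vapply(ch[[i]], rec, ""), collapse = ","), ")")
  }
  paste0(rec(1L), ";")
}

# canonical string form of one split: the side containing the first leaf in
# sorted order of the full leaf set, labels sorted and joined with "|"
canonical_split <- function(side, all_leaves) {
  first <- sort(all_leaves)[1]
  if (!(first %in% side)) side <- setdiff(all_leaves, side)
  paste(sort(side), collapse = "|")
}

#' Non-trivial bipartitions of a topology
#'
#' Returns the set of unrooted splits induced by internal edges, each in a
#' canonical form (the side containing the alphabetically first leaf, sorted
#' and joined with `|`). Splits with a singleton or full-set side are
#' excluded; the two root edges of a bifurcating root induce the same split
#' and are counted once.
#'
#' @param t a [topology()]
#' @return character vector of canonical splits (possibly empty), sorted
#' @export
bipartitions <- function(t) {
  leaves <- leaf_labels(t)
  n <- length(leaves)
  if (n < 4L) return(character(0))
  dl <- descendant_leaves(t)
  keep <- which(!t$is_leaf & seq_len(n_nodes(t)) != 1L)
  out <- character(0)
  for (i in keep) {
    sz <- length(dl[[i]])
    if (sz >= 2L && sz <= n - 2L)
      out <- c(out, canonical_split(dl[[i]], leaves))
  }
  sort(unique(out))
}

#' Robinson-Foulds distance between two topologies
#'
#' The number of non-trivial unrooted bipartitions present in exactly one of
#' the two trees (size of the symmetric difference of their split sets).
#' Both trees must be over the same leaf set.
#'
#' @param t1,t2 [topology()] objects with identical leaf labels
#' @return non-negative integer
#' @examples
#' rf <- robinson_foulds(parse_newick("((A,B),(C,D));"),
#'                       parse_newick("((A,C),(B,D));"))  # 2
#' @export
robinson_foulds <- function(t1, t2) {
  l1 <- sort(leaf_labels(t1)); l2 <- sort(leaf_labels(t2))
  if (!identical(l1, l2)) {
    diff <- c(setdiff(l1, l2), setdiff(l2, l1))
    stop("leaf sets differ; symmetric difference: ", paste(diff, collapse = ", "))
  }
  b1 <- bipartitions(t1); b2 <- bipartitions(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

# are two leaf-subset clusters compatible (nested or disjoint)?
clusters_compatible <- function(a, b) {
  i <- length(intersect(a, b))
  i == 0L || i == length(a) || i == length(b)
}

# build a topology from a set of pairwise-compatible clusters over `leaves`
# (the full set and singletons are added implicitly)
tree_from_clusters <- function(clusters, leaves) {
  clusters <- clusters[vapply(clusters, length, 0L) >= 2L]
  clusters <- clusters[vapply(clusters, length, 0L) < length(leaves)]
  keys <- vapply(clusters, function(s) paste(sort(s), collapse = "|"), "")
  clusters <- clusters[!duplicated(keys)]
  sizes <- vapply(clusters, length, 0L)
  ord <- order(-sizes)           # parents before children
  clusters <- clusters[ord]
  parent <- 0L; label <- ""      # node 1 = root (full leaf set)
  node_cluster <- list(leaves)
  attach_under <- function(set) {
    # deepest existing node whose cluster contains `set`
    best <- 1L
    for (k in seq_along(node_cluster)) {
      ck <- node_cluster[[k]]
      if (length(ck) >= length(set) && all(set %in% ck) &&
          length(ck) < length(node_cluster[[best]])) best <- k
    }
    best
  }
  for (cl in clusters) {
    parent <- c(parent, attach_under(cl))
    label <- c(label, "")
    node_cluster[[length(parent)]] <- cl
  }
  for (lf in leaves) {
    parent <- c(parent, attach_under(lf))
    label <- c(label, lf)
    node_cluster[[length(parent)]] <- lf
  }
  # renumber to preorder
  n <- length(parent)
  kids <- vector("list", n)
  for (i in seq_len(n)[-1]) kids[[parent[i]]] <- c(kids[[parent[i]]], i)
  new_parent <- integer(n); new_label <- character(n)
  new_id <- integer(n); cnt <- 0L
  stack <- list(c(1L, 0L))
  while (length(stack)) {
    top <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    cnt <- cnt + 1L
    new_id[top[1]] <- cnt
    new_parent[cnt] <- top[2]
    new_label[cnt] <- label[top[1]]
    for (c_ in rev(kids[[top[1]]])) stack[[length(stack) + 1L]] <- c(c_, cnt)
  }
  topology(new_parent, new_label)
}

#' Greedy supertree from a collection of topologies
#'
#' Combines the rooted clusters (descendant leaf sets of internal nodes) of
#' all input trees over the union of their leaves. Clusters are ranked by
#' frequency across input trees (descending), then by size (ascending), then
#' lexically by canonical form, and greedily accepted when compatible
#' (nested or disjoint) with every cluster already accepted. The tree built
#' from the accepted clusters is returned; contradictory inputs therefore
#' yield a partially unresolved tree rather than an error.
#'
#' When all inputs are topologically identical the output equals them.
#'
#' @param trees list of [topology()] objects (at least one)
#' @return a [topology()] over the union of the input leaf sets
#' @export
build_supertree <- function(trees) {
  stopifnot(is.list(trees), length(trees) >= 1L)
  leaves <- sort(unique(unlist(lapply(trees, leaf_labels))))
  if (!length(leaves)) stop("no leaves in input trees")
  tab <- new.env(parent = emptyenv())
  for (t in trees) {
    dl <- descendant_leaves(t)
    idx <- which(!t$is_leaf)
    seen <- character(0)
    for (i in idx) {
      cl <- sort(dl[[i]])
      if (length(cl) < 2L) next
      key <- paste(cl, collapse = "|")
      if (key %in% seen) next    # count once per tree
      seen <- c(seen, key)
      prev <- if (!is.null(tab[[key]])) tab[[key]] else 0L
      tab[[key]] <- prev + 1L
    }
  }
  keys <- ls(tab)
  if (!length(keys)) return(tree_from_clusters(list(), leaves))
  freq <- vapply(keys, function(k) tab[[k]], 0L)
  sets <- strsplit(keys, "|", fixed = TRUE)
  sizes <- vapply(sets, length, 0L)
  ord <- order(-freq, sizes, keys)
  accepted <- list()
  for (k in ord) {
    cand <- sets[[k]]
    if (length(cand) >= length(leaves)) next
    ok <- all(vapply(accepted, clusters_compatible, TRUE, b = cand))
    if (ok) accepted[[length(accepted) + 1L]] <- cand
  }
  tree_from_clusters(accepted, leaves)
}

#' Prune leaves from a topology
#'
#' Removes the given leaves, suppresses any internal node left with a single
#' child, renumbers the remaining nodes in preorder, and reports the mapping
#' from old to new node ids.
#'
#' @param t a [topology()]
#' @param drop character vector of leaf labels to remove (strict subset of
#'   the leaves; may be empty)
#' @return list with `topology` (the pruned tree) and `map` (integer vector
#'   over old node ids; `NA` where the node was removed or suppressed)
#' @examples
#' pr <- prune_leaves(parse_newick("((A,B),(C,D));"), "D")
#' serialize_newick(pr$topology)  # "((A,B),C);"
#' @export
prune_leaves <- function(t, drop) {
  drop <- as.character(drop)
  leaves <- leaf_labels(t)
  if (length(drop) == 0L)
    return(list(topology = t, map = seq_len(n_nodes(t))))
  unknown <- setdiff(drop, leaves)
  if (length(unknown))
    stop("unknown leaf labels: ", paste(unknown, collapse = ", "))
  if (length(setdiff(leaves, drop)) == 0L)
    stop("cannot drop all leaves")
  n <- n_nodes(t)
  keep <- rep(TRUE, n)
  keep[t$is_leaf & t$label %in% drop] <- FALSE
  # iteratively remove childless internals, then suppress unary chains
  repeat {
    nch <- integer(n)
    for (i in seq_len(n)[-1])
      if (keep[i] && keep[t$parent[i]]) nch[t$parent[i]] <- nch[t$parent[i]] + 1L
    dead <- keep & !t$is_leaf & nch == 0L
    if (!any(dead)) break
    keep[dead] <- FALSE
  }
  # effective parent skipping removed nodes
  eff_parent <- function(i) {
    p <- t$parent[i]
    while (p != 0L && !keep[p]) p <- t$parent[p]
    p
  }
  nch <- integer(n)
  for (i in seq_len(n)[-1]) if (keep[i]) {
    p <- eff_parent(i)
    if (p != 0L) nch[p] <- nch[p] + 1L
  }
  suppress <- keep & !t$is_leaf & nch == 1L
  # a suppressed (or unary) root chain: keep walking until a node with >= 2
  # children or a leaf becomes the new root
  alive <- keep & !suppress
  parent_of <- function(i) {
    p <- t$parent[i]
    while (p != 0L && !alive[p]) p <- t$parent[p]
    p
  }
  alive_ids <- which(alive)
  par_alive <- vapply(alive_ids, parent_of, 0L)
  root_id <- alive_ids[par_alive == 0L]
  if (length(root_id) != 1L) root_id <- root_id[1]
  kids <- vector("list", n)
  for (k in seq_along(alive_ids)) {
    i <- alive_ids[k]; p <- par_alive[k]
    if (p != 0L && i != root_id) kids[[p]] <- c(kids[[p]], i)
  }
  map <- rep(NA_integer_, n)
  new_parent <- integer(0); new_label <- character(0)
  cnt <- 0L
  stack <- list(c(root_id, 0L))
  while (length(stack)) {
    top <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    cnt <- cnt + 1L
    map[top[1]] <- cnt
    new_parent[cnt] <- top[2]
    new_label[cnt] <- t$label[top[1]]
    for (c_ in rev(kids[[top[1]]])) stack[[length(stack) + 1L]] <- c(c_, cnt)
  }
  list(topology = topology(new_parent, new_label), map = map)
}

#' Star topology over a set of taxa
#'
#' A root with every taxon attached directly: the no-phylogeny comparator
#' used for plain per-taxon logistic fits.
#'
#' @param labels character vector of taxon names (length >= 1)
#' @return a [topology()]
#' @export
star_topology <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) == 1L) return(topology(0L, labels))
  topology(c(0L, rep(1L, length(labels))), c("", labels))
}

#' Nearest surviving ancestor after pruning
#'
#' Walks up from a node of the original topology until it reaches an
#' ancestor that survived a [prune_leaves()] operation, and returns that
#' ancestor's id in the pruned topology. When every ancestor was suppressed
#' (the node hung directly off a root that became unary) the pruned root is
#' returned, the closest remaining ancestral position.
#'
#' @param t the original [topology()]
#' @param node_id node id in `t`
#' @param map the `map` component returned by [prune_leaves()]
#' @return integer node id in the pruned topology
#' @export
nearest_surviving_ancestor <- function(t, node_id, map) {
  p <- t$parent[node_id]
  while (p != 0L) {
    if (!is.na(map[p])) return(map[p])
    p <- t$parent[p]
  }
  1L
}
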