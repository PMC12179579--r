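#' Parse a newick string into a rooted tree
#'
#' Thin, validating wrapper around [ape::read.tree()]. Internal-node
#' labels are interpreted as support values (the RAxML convention used
#' throughout the package), and are available to
#' [collapse_low_support()]. Trees are treated as rooted; polytomies are
#' allowed.
#'
#' @param text A newick string describing one tree.
#' @return An object of class `"phylo"`.
#' @details Parsing fails with an informative error on malformed
#'   parentheses or duplicated tip labels; `ape` alone accepts
#'   duplicated labels silently, which would corrupt all downstream
#'   bipartition accounting.
#' @examples
#' tr <- parse_newick("((A:1,B:2)90:3,C:4);")
#' tr$node.label
#' @seealso [read_newick()] for files, [write_newick()]
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (sum(gregexpr("(", text, fixed = TRUE)[[1]] > 0) !=
      sum(gregexpr(")", text, fixed = TRUE)[[1]] > 0)) {
    stop("malformed newick: unbalanced parentheses in ", sQuote(text))
  }
  tr <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("malformed newick: ", conditionMessage(e)),
    warning = function(w) stop("malformed newick: ", conditionMessage(w))
  )
  if (is.null(tr)) stop("malformed newick: ", sQuote(text))
  validate_tree(tr)
  tr
}

#' Read one or more newick trees from a file
#'
#' @param file Path to a newick file (one tree per line, or a multi-tree
#'   file).
#' @return A `"multiPhylo"` list of trees (even for a single tree, for
#'   predictable downstream handling).
#' @export
read_newick <- function(file) {
  trs <- ape::read.tree(file)
  if (is.null(trs)) stop("no trees could be read from ", file)
  if (inherits(trs, "phylo")) trs <- structure(list(trs), class = "multiPhylo")
  lapply(trs, validate_tree)
  trs
}

#' Write trees to newick
#'
#' @param trees A `"phylo"` or `"multiPhylo"` object.
#' @param file Optional path; when `NULL` the newick string(s) are
#'   returned.
#' @return Newick string(s), invisibly when written to file.
#' @export
write_newick <- function(trees, file = NULL) {
  out <- ape::write.tree(trees)
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

# Tip-label uniqueness and basic shape checks shared by all entry points.
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object")
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup)) {
    stop("duplicate tip label(s): ", paste(sQuote(dup), collapse = ", "))
  }
  if (any(!nzchar(tree$tip.label))) stop("empty tip label")
  invisible(tree)
}

#' Prune a tree to a set of taxa
#'
#' Retains `keep` (intersected with the tree's tips), suppressing unary
#' nodes and summing branch lengths along suppressed paths, so that the
#' bipartitions of the result equal the restriction of the original
#' bipartitions to the kept taxa.
#'
#' @param tree A `"phylo"` object.
#' @param keep Character vector of tip labels to retain.
#' @return The pruned `"phylo"` object.
#' @examples
#' tr <- parse_newick("((A,B),(C,(D,E)));")
#' write_newick(prune_to_taxa(tr, c("A", "C", "D")))
#' @export
prune_to_taxa <- function(tree, keep) {
  keep <- intersect(tree$tip.label, keep)
  if (length(keep) == 0L) {
    stop("no taxa to keep: the intersection of 'keep' with the tree's tips is empty")
  }
  if (length(keep) == length(tree$tip.label)) return(tree)
  if (length(keep) == 1L) {
    # single-tip tree: ape cannot represent it via keep.tip
    d <- if (is.null(tree$edge.length)) NULL else
      ape::node.depth.edgelength(tree)[match(keep, tree$tip.label)]
    tr <- list(edge = matrix(c(2L, 1L), 1L, 2L), tip.label = keep,
               Nnode = 1L)
    if (!is.null(d)) tr$edge.length <- d
    class(tr) <- "phylo"
    return(tr)
  }
  ape::keep.tip(tree, keep)
}

#' Collapse poorly supported branches into polytomies
#'
#' Contracts every internal edge whose child-node support is strictly
#' below `threshold`. Tips are untouched; the contracted edge's length
#' is absorbed into the resulting polytomy (i.e. dropped), matching the
#' usual treatment of collapsed bootstrap branches.
#'
#' @param tree A `"phylo"` with numeric `node.label` support values
#'   (root label may be empty).
#' @param threshold Support threshold; edges with support `< threshold`
#'   are collapsed.
#' @return A `"phylo"`, possibly with polytomies.
#' @export
collapse_low_support <- function(tree, threshold) {
  ntip <- length(tree$tip.label)
  if (tree$Nnode < 2L || threshold <= 0) return(tree)
  if (is.null(tree$node.label)) {
    stop("tree has no node support values (node.label is NULL)")
  }
  sup <- suppressWarnings(as.numeric(tree$node.label))
  root <- ntip + 1L
  internal <- seq.int(ntip + 1L, ntip + tree$Nnode)
  nonroot <- setdiff(internal, root)
  miss <- nonroot[is.na(sup[nonroot - ntip])]
  if (length(miss)) {
    stop("missing support value at internal node(s): ",
         paste(miss, collapse = ", "))
  }
  kill <- nonroot[sup[nonroot - ntip] < threshold]
  if (!length(kill)) return(tree)
  contract_nodes(tree, kill)
}

# Contract the edges above the given internal nodes (never the root).
# Children of a contracted node are re-attached to its nearest
# surviving ancestor; the contracted edge's length is dropped.
contract_nodes <- function(tree, kill) {
  ntip <- length(tree$tip.label)
  parent <- integer(ntip + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  elen <- tree$edge.length
  has_len <- !is.null(elen)
  len_of <- numeric(ntip + tree$Nnode)
  if (has_len) len_of[tree$edge[, 2L]] <- elen

  surviving_parent <- function(v) {
    p <- parent[v]
    while (p %in% kill) p <- parent[p]
    p
  }
  keep_children <- function(v) {
    kids <- tree$edge[tree$edge[, 1L] == v, 2L]
    out <- list()
    for (k in kids) {
      if (k %in% kill) out <- c(out, keep_children(k)) else out <- c(out, k)
    }
    out
  }
  # rebuild recursively from the root as a newick string, then reparse
  sup <- tree$node.label
  build <- function(v) {
    if (v <= ntip) {
      s <- tree$tip.label[v]
    } else {
      kids <- unlist(keep_children(v))
      s <- paste0("(", paste(vapply(kids, build, ""), collapse = ","), ")")
      if (!is.null(sup)) s <- paste0(s, sup[v - ntip])
    }
    if (has_len && v != ntip + 1L) s <- paste0(s, ":", format(len_of[v], digits = 15))
    s
  }
  parse_newick(paste0(build(ntip + 1L), ";"))
}

#' Re-root a tree on an outgroup
#'
#' @param tree A `"phylo"` object.
#' @param outgroup Tip label(s) forming the outgroup.
#' @return The re-rooted `"phylo"`.
#' @export
root_on_outgroup <- function(tree, outgroup) {
  missing <- setdiff(outgroup, tree$tip.label)
  if (length(missing)) {
    stop("outgroup taxa not in tree: ", paste(sQuote(missing), collapse = ", "))
  }
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}

## ---- bipartition machinery -------------------------------------------------

# List of tip-label sets for each node (tips + internal), by postorder
# accumulation over the edge matrix.
node_tip_sets <- function(tree) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  sets <- vector("list", nn)
  for (i in seq_len(ntip)) sets[[i]] <- tree$tip.label[i]
  eo <- if (is.null(attr(tree, "order")) || attr(tree, "order") != "postorder")
    ape::reorder.phylo(tree, "postorder") else tree
  for (e in seq_len(nrow(eo$edge))) {
    p <- eo$edge[e, 1L]
    ch <- eo$edge[e, 2L]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  sets
}

# Canonical key of a split given its two sides (character vectors).
# The lexicographically smallest sorted side string is stored first so
# that equality is representation-independent.
split_key <- function(a, b) {
  sa <- paste(sort(a), collapse = ",")
  sb <- paste(sort(b), collapse = ",")
  if (sa <= sb) paste(sa, sb, sep = " | ") else paste(sb, sa, sep = " | ")
}

# A split object: list(a=, b=, key=)
make_split <- function(a, b) list(a = a, b = b, key = split_key(a, b))

# Restrict a split to a taxon subset; NULL when it becomes trivial
# (an empty side, or fewer than 3 taxa overall so that no internal edge
# could witness it).
restrict_split <- function(s, taxa) {
  a <- intersect(s$a, taxa)
  b <- intersect(s$b, taxa)
  if (length(a) == 0L || length(b) == 0L || length(a) + length(b) < 3L) {
    return(NULL)
  }
  make_split(a, b)
}

# Two splits on overlapping taxon sets conflict iff all four pairwise
# side intersections are non-empty (standard split compatibility).
splits_conflict <- function(s1, s2) {
  length(intersect(s1$a, s2$a)) > 0L &&
    length(intersect(s1$a, s2$b)) > 0L &&
    length(intersect(s1$b, s2$a)) > 0L &&
    length(intersect(s1$b, s2$b)) > 0L
}

#' Non-trivial bipartitions of a tree
#'
#' Returns the bipartitions induced by the internal edges of the tree
#' (sides given as tip-label sets, with a canonical key so equality is
#' well-defined), optionally restricted to a taxon subset. Splits that
#' become trivial under restriction (an empty side, or fewer than three
#' taxa in total) are dropped. Complementary duplicates (the two edges
#' below a binary root) are de-duplicated.
#'
#' @param tree A `"phylo"` object.
#' @param restrict_to Optional character vector of taxa to restrict to.
#' @return A list of splits, each a list with elements `a`, `b` (the two
#'   sides) and `key` (canonical string form).
#' @details Under restriction, a split is kept only while some witnessing
#'   edge would remain internal in the pruned tree: its clade side must
#'   retain at least two taxa (an edge whose clade shrinks to one taxon
#'   becomes that taxon's pendant edge) and its complement at least one.
#'   With this rule `bipartitions(prune_to_taxa(t, S))` equals
#'   `bipartitions(t, restrict_to = S)` exactly.
#' @examples
#' bipartitions(parse_newick("((A,B),(C,D));"))[[1]]$key
#' @export
bipartitions <- function(tree, restrict_to = NULL) {
  ntip <- length(tree$tip.label)
  if (ntip < 3L || tree$Nnode < 2L) return(list())
  all_tips <- tree$tip.label
  sets <- node_tip_sets(tree)
  root <- ntip + 1L
  internal <- setdiff(seq.int(ntip + 1L, ntip + tree$Nnode), root)
  out <- list()
  seen <- character(0)
  for (v in internal) {
    a <- sets[[v]]
    b <- setdiff(all_tips, a)
    if (length(a) == 0L || length(b) == 0L) next
    if (!is.null(restrict_to)) {
      a <- intersect(a, restrict_to)
      b <- intersect(b, restrict_to)
      if (length(a) < 2L || length(b) < 1L) next
    }
    s <- make_split(a, b)
    if (s$key %in% seen) next
    seen <- c(seen, s$key)
    out <- c(out, list(s))
  }
  out
}

# Internal: splits per node (node id -> split or NULL), used by the
# concordance module where node identity matters. Root maps to NULL.
node_splits <- function(tree) {
  ntip <- length(tree$tip.label)
  all_tips <- tree$tip.label
  sets <- node_tip_sets(tree)
  root <- ntip + 1L
  ids <- seq.int(ntip + 1L, ntip + tree$Nnode)
  out <- vector("list", length(ids))
  names(out) <- as.character(ids)
  for (i in seq_along(ids)) {
    v <- ids[i]
    if (v == root) next
    a <- sets[[v]]
    b <- setdiff(all_tips, a)
    if (length(a) >= 1L && length(b) >= 1L) out[[i]] <- make_split(a, b)
  }
  out
}

# Canonical topology string: branch lengths and supports ignored,
# children sorted recursively, so two trees have equal strings iff they
# are the same rooted topology.
canonical_topology <- function(tree) {
  ntip <- length(tree$tip.label)
  children <- vector("list", ntip + tree$Nnode)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1L]
    children[[p]] <- c(children[[p]], tree$edge[e, 2L])
  }
  build <- function(v) {
    if (v <= ntip) return(tree$tip.label[v])
    parts <- sort(vapply(children[[v]], build, ""))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  paste0(build(ntip + 1L), ";")
}

# TRUE when every internal node of a rooted tree has exactly 2 children.
is_fully_resolved <- function(tree) {
  tree$Nnode == length(tree$tip.label) - 1L
}
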