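#' Per-node gene-tree concordance against a species tree
#'
#' For every internal node of the (rooted) species tree, classifies each
#' gene tree as concordant, conflicting, or uninformative with respect
#' to the bipartition the node defines, in the style of PhyParts-type
#' concordance accounting.
#'
#' A gene tree is scored against the node's split restricted to the
#' gene tree's tip set. When the restriction is trivial (a side lost
#' entirely, or fewer than three shared taxa) the gene tree is
#' uninformative for that node. Otherwise the gene tree is concordant
#' if one of its own splits equals the restricted split, conflicting if
#' at least one of its splits is incompatible with it (all four
#' pairwise side intersections non-empty), and uninformative otherwise
#' (e.g. the relevant branches were collapsed into a polytomy).
#'
#' @param species_tree Rooted `"phylo"` reference tree.
#' @param gene_trees A `"multiPhylo"` or list of `"phylo"` gene trees;
#'   each gene tree's tips must occur in the species tree (missing taxa
#'   are allowed).
#' @return A data frame of class `"node_concordance"` with one row per
#'   internal species-tree node: `node_id` (ape node number),
#'   `split` (canonical split string; `NA` for the root), `concordant`,
#'   `conflicting`, `uninformative`, `top_alt_split` (most frequent
#'   conflicting split, ties broken lexicographically), and
#'   `top_alt_count`. The root row carries `NA` counts: the root does
#'   not define a split.
#' @examples
#' sp <- parse_newick("((A,B),(C,D));")
#' gt <- lapply(c("((A,B),(C,D));", "((A,B),(C,D));",
#'                "((A,C),(B,D));", "((A,B),C);"), parse_newick)
#' node_concordance(sp, gt)
#' @export
node_concordance <- function(species_tree, gene_trees) {
  gene_trees <- as_tree_list(gene_trees)
  sp_tips <- species_tree$tip.label
  for (g in gene_trees) {
    extra <- setdiff(g$tip.label, sp_tips)
    if (length(extra)) {
      stop("gene-tree tip(s) not present in the species tree: ",
           paste(sQuote(extra), collapse = ", "))
    }
  }
  nsp <- node_splits(species_tree)
  gene_splits <- lapply(gene_trees, bipartitions)
  gene_tips <- lapply(gene_trees, function(g) g$tip.label)
  n_genes <- length(gene_trees)

  rows <- lapply(seq_along(nsp), function(i) {
    s <- nsp[[i]]
    nid <- as.integer(names(nsp)[i])
    if (is.null(s)) {
      return(data.frame(node_id = nid, split = NA_character_,
                        concordant = NA_integer_, conflicting = NA_integer_,
                        uninformative = NA_integer_,
                        top_alt_split = NA_character_,
                        top_alt_count = NA_integer_,
                        stringsAsFactors = FALSE))
    }
    conc <- 0L
    conf <- 0L
    uninf <- 0L
    alt_tally <- new.env(parent = emptyenv())
    for (k in seq_len(n_genes)) {
      cls <- classify_gene_at_split(s, gene_splits[[k]], gene_tips[[k]])
      if (cls$status == "concordant") {
        conc <- conc + 1L
      } else if (cls$status == "conflicting") {
        conf <- conf + 1L
        for (key in cls$alternatives) {
          prev <- if (is.null(alt_tally[[key]])) 0L else alt_tally[[key]]
          alt_tally[[key]] <- prev + 1L
        }
      } else {
        uninf <- uninf + 1L
      }
    }
    keys <- ls(alt_tally)
    if (length(keys)) {
      counts <- vapply(keys, function(k) alt_tally[[k]], integer(1))
      best <- max(counts)
      top <- sort(keys[counts == best])[1L]  # deterministic tie-break
      top_n <- best
    } else {
      top <- NA_character_
      top_n <- 0L
    }
    data.frame(node_id = nid, split = s$key, concordant = conc,
               conflicting = conf, uninformative = uninf,
               top_alt_split = top, top_alt_count = top_n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_genes") <- n_genes
  class(out) <- c("node_concordance", class(out))
  out
}

# Classify one gene tree at one species-tree split.
classify_gene_at_split <- function(split, g_splits, g_tips) {
  r <- restrict_split(split, g_tips)
  if (is.null(r)) return(list(status = "uninformative"))
  universe <- c(r$a, r$b)
  alts <- character(0)
  concord <- FALSE
  for (gs in g_splits) {
    gr <- restrict_split(gs, universe)
    if (is.null(gr)) next
    if (gr$key == r$key) {
      concord <- TRUE
      break
    }
    if (splits_conflict(gr, r)) alts <- c(alts, gr$key)
  }
  if (concord) return(list(status = "concordant"))
  if (length(alts)) {
    return(list(status = "conflicting", alternatives = unique(alts)))
  }
  list(status = "uninformative")
}

#' Pie-chart fractions for one concordance row
#'
#' Splits the gene-tree total at a node into the four fractions
#' conventionally drawn as node pies: concordant, the single most
#' common conflicting topology, all other conflict, and uninformative.
#'
#' @param nc A one-row subset of a [node_concordance()] result (or any
#'   list with `concordant`, `conflicting`, `uninformative`,
#'   `top_alt_count`).
#' @return Named numeric vector `(concordant, top_conflict,
#'   other_conflict, uninformative)` summing to 1.
#' @export
pie_fractions <- function(nc) {
  tot <- nc$concordant + nc$conflicting + nc$uninformative
  if (is.na(tot) || tot == 0) stop("no gene trees at this node")
  c(concordant = nc$concordant / tot,
    top_conflict = nc$top_alt_count / tot,
    other_conflict = (nc$conflicting - nc$top_alt_count) / tot,
    uninformative = nc$uninformative / tot)
}

#' Taxon-removal jackknife of node concordance
#'
#' Recomputes per-node concordance after removing chosen taxa from the
#' species tree and from every gene tree, and reports the change in
#' concordant counts node by node. This attributes support erosion at
#' particular nodes to rogue taxa whose placement wanders among gene
#' trees.
#'
#' @param species_tree Rooted `"phylo"` reference tree.
#' @param gene_trees `"multiPhylo"` or list of gene trees.
#' @param removals A list of character vectors; each vector is one set
#'   of taxa to remove jointly (so synergistic removals are one
#'   element). A zero-length element is allowed and yields an identical
#'   before/after pair.
#' @return A list of class `"jackknife_report"`, one element per
#'   removal set, each a data frame with columns `node_id`, `split`,
#'   `concordant_before`, `conflicting_before`, `uninformative_before`,
#'   `concordant_after`, `conflicting_after`, `uninformative_after`,
#'   `delta_concordant`. Nodes whose split becomes trivial after
#'   removal carry `NA` after-counts.
#' @export
taxon_jackknife <- function(species_tree, gene_trees, removals) {
  gene_trees <- as_tree_list(gene_trees)
  if (is.character(removals)) removals <- list(removals)
  before <- node_concordance(species_tree, gene_trees)
  all_tips <- species_tree$tip.label
  out <- lapply(removals, function(rem) {
    bad <- setdiff(rem, all_tips)
    if (length(bad)) {
      stop("removal taxa not in species tree: ",
           paste(sQuote(bad), collapse = ", "))
    }
    keep <- setdiff(all_tips, rem)
    if (length(keep) == 0L) stop("cannot remove every taxon")
    if (length(rem) == 0L) {
      res <- before
      return(bind_jackknife(before, before,
                            match(before$node_id, before$node_id)))
    }
    sp2 <- prune_to_taxa(species_tree, keep)
    genes2 <- lapply(gene_trees, function(g) {
      k <- intersect(g$tip.label, keep)
      if (length(k) < 2L) return(NULL)
      prune_to_taxa(g, k)
    })
    genes2 <- genes2[!vapply(genes2, is.null, logical(1))]
    after <- node_concordance(sp2, genes2)
    # match original nodes to pruned-tree nodes via restricted splits
    nsp_before <- node_splits(species_tree)
    restr_keys <- vapply(before$node_id, function(nid) {
      s <- nsp_before[[as.character(nid)]]
      if (is.null(s)) return(NA_character_)
      r <- restrict_split(s, keep)
      if (is.null(r)) NA_character_ else r$key
    }, character(1))
    idx <- match(restr_keys, after$split)
    bind_jackknife(before, after, idx)
  })
  names(out) <- vapply(removals, paste, "", collapse = "+")
  class(out) <- c("jackknife_report", class(out))
  out
}

bind_jackknife <- function(before, after, idx) {
  data.frame(
    node_id = before$node_id,
    split = before$split,
    concordant_before = before$concordant,
    conflicting_before = before$conflicting,
    uninformative_before = before$uninformative,
    concordant_after = after$concordant[idx],
    conflicting_after = after$conflicting[idx],
    uninformative_after = after$uninformative[idx],
    delta_concordant = after$concordant[idx] - before$concordant,
    stringsAsFactors = FALSE
  )
}

# Accept multiPhylo or plain lists.
as_tree_list <- function(x) {
  if (inherits(x, "phylo")) return(list(x))
  if (inherits(x, "multiPhylo")) return(unclass(x))
  stopifnot(is.list(x))
  x
}
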