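#' Number of rooted binary topologies on k labeled tips
#'
#' The double factorial \eqn{(2k-3)!! = 1 \times 3 \times \cdots \times
#' (2k-3)}, the number of distinct rooted, binary, fully resolved tree
#' shapes on k labeled tips.
#'
#' @param k Number of tips (k >= 2).
#' @return The count as a double. Exact for k <= 16 (the product stays
#'   below 2^53); beyond that the value is a correctly rounded double.
#' @examples
#' count_rooted_topologies(4)   # 15
#' count_rooted_topologies(13)  # 316234143225, i.e. ~3.16e11
#' @export
count_rooted_topologies <- function(k) {
  if (!is.numeric(k) || length(k) != 1L || k != round(k) || k < 2) {
    stop("'k' must be a single integer >= 2")
  }
  if (k == 2) return(1)
  prod(seq(1, 2 * k - 3, by = 2))
}

#' Define a clade map for scenario testing
#'
#' A clade map names the monophyletic groups whose inter-relationships
#' are under test (each contributes one representative tip per draw)
#' plus the individual taxa held fixed in every test.
#'
#' @param clades Named list of character vectors; names are clade
#'   labels, members are taxon labels. Clades must be pairwise disjoint.
#' @param fixed Character vector of taxa always retained under their own
#'   labels (default none). Must be disjoint from all clades.
#' @return A list of class `"clade_map"` with elements `clades`,
#'   `fixed`, and `k` (tip count of the reduced problem).
#' @export
clade_map <- function(clades, fixed = character(0)) {
  stopifnot(is.list(clades), length(clades) >= 1L)
  if (is.null(names(clades)) || any(!nzchar(names(clades)))) {
    stop("every clade must be named")
  }
  if (anyDuplicated(names(clades))) stop("duplicate clade names")
  sizes <- lengths(clades)
  if (any(sizes == 0L)) {
    stop("empty clade(s): ",
         paste(sQuote(names(clades)[sizes == 0L]), collapse = ", "))
  }
  members <- unlist(clades, use.names = FALSE)
  if (anyDuplicated(members)) {
    stop("clades are not pairwise disjoint: ",
         paste(sQuote(unique(members[duplicated(members)])), collapse = ", "))
  }
  if (length(intersect(members, fixed))) {
    stop("fixed taxa overlap clade members: ",
         paste(sQuote(intersect(members, fixed)), collapse = ", "))
  }
  structure(list(clades = clades[order(names(clades))], fixed = sort(fixed),
                 k = length(clades) + length(fixed)),
            class = "clade_map")
}

#' Draw representative taxa for each clade
#'
#' Each draw selects one member per clade uniformly at random (clades
#' are processed in alphabetical order so the draw sequence is a pure
#' function of the seed) and appends all fixed taxa.
#'
#' @param cm A [clade_map()].
#' @param n_draws Number of draws.
#' @param seed Integer RNG seed.
#' @return A list of `n_draws` named character vectors; names identify
#'   the clade each representative stands for (fixed taxa are named by
#'   themselves).
#' @export
draw_representatives <- function(cm, n_draws, seed) {
  stopifnot(inherits(cm, "clade_map"), n_draws >= 1)
  with_seed(seed, {
    lapply(seq_len(n_draws), function(i) {
      reps <- vapply(cm$clades, function(m) m[sample.int(length(m), 1L)], "")
      out <- c(reps, stats::setNames(cm$fixed, cm$fixed))
      out
    })
  })
}

#' Enumerate candidate clade-level topologies from pruned gene trees
#'
#' Candidates are the distinct fully resolved rooted topologies observed
#' among the pruned, clade-relabeled gene trees (mode `"observed"`), or
#' the single majority-rule consensus of them (mode `"consensus"`),
#' filtered to trees with exactly `required_nodes` internal nodes.
#'
#' @param pruned_trees List of pruned gene trees whose tips are clade
#'   names and fixed taxa.
#' @param required_nodes Internal-node count a fully resolved candidate
#'   must have (k - 1 for k tips).
#' @param mode `"observed"` (default) or `"consensus"`.
#' @return A named list of `"phylo"` topologies keyed by canonical
#'   newick; empty (with a warning) when no pruned tree is fully
#'   resolved.
#' @export
enumerate_candidates <- function(pruned_trees, required_nodes,
                                 mode = c("observed", "consensus")) {
  mode <- match.arg(mode)
  pruned_trees <- as_tree_list(pruned_trees)
  if (mode == "consensus") {
    cons <- ape::consensus(pruned_trees, p = 0.5, rooted = TRUE)
    if (cons$Nnode != required_nodes) {
      warning("majority consensus is not fully resolved; no candidate")
      return(list())
    }
    key <- canonical_topology(cons)
    return(stats::setNames(list(cons), key))
  }
  keep <- vapply(pruned_trees, function(tr) tr$Nnode == required_nodes, NA)
  if (!any(keep)) {
    warning("no fully resolved pruned gene tree; candidate set is empty")
    return(list())
  }
  trees <- pruned_trees[keep]
  keys <- vapply(trees, canonical_topology, "")
  first <- !duplicated(keys)
  out <- trees[first]
  names(out) <- keys[first]
  # strip lengths/supports: candidates are pure topologies
  out <- lapply(out, function(tr) {
    tr$edge.length <- NULL
    tr$node.label <- NULL
    tr
  })
  out[order(names(out))]
}

#' Score a candidate topology against pruned gene trees
#'
#' The support score of a candidate is the mean number of concordant
#' gene trees per internal node, excluding the root (the root defines
#' no bipartition; its two child nodes are scored as ordinary nodes).
#'
#' @param candidate A `"phylo"` topology on the clade-level tip set.
#' @param pruned_trees Gene trees pruned and relabeled to the same tip
#'   set (taxon subsets are tolerated and contribute as uninformative
#'   where they cannot witness a node).
#' @return A list with `score` (mean concordant count over scored
#'   nodes) and `per_node` (the [node_concordance()] table restricted to
#'   non-root nodes).
#' @export
score_topology <- function(candidate, pruned_trees) {
  pruned_trees <- as_tree_list(pruned_trees)
  cand_tips <- sort(candidate$tip.label)
  all_gene_tips <- sort(unique(unlist(lapply(pruned_trees,
                                             function(g) g$tip.label))))
  if (length(setdiff(all_gene_tips, cand_tips))) {
    stop("gene-tree tips not in candidate: ",
         paste(sQuote(setdiff(all_gene_tips, cand_tips)), collapse = ", "))
  }
  nc <- node_concordance(candidate, pruned_trees)
  scored <- nc[!is.na(nc$concordant), , drop = FALSE]
  list(score = mean(scored$concordant), per_node = scored)
}

#' Rank alternative topology scenarios
#'
#' The full scenario test: for each of `n_draws` random representative
#' selections, gene trees are pruned to one representative per clade
#' plus the fixed taxa and relabeled to clade names; candidate fully
#' resolved topologies are enumerated from the pruned trees; and every
#' candidate (from any draw) is scored on every draw's pruned gene
#' set. Per-candidate scores are averaged over draws and ranked.
#'
#' @param species_tree Rooted species tree (used to report the
#'   reference clade-level topology's rank; may be `NULL`).
#' @param gene_trees `"multiPhylo"` or list of gene trees.
#' @param cm A [clade_map()].
#' @param n_draws Number of representative draws.
#' @param seed Integer RNG seed.
#' @param top_n Number of top-ranked scenarios to return (default 12).
#' @param mode Candidate enumeration mode, see [enumerate_candidates()].
#' @param outgroup Optional clade name or fixed taxon on which every
#'   pruned gene tree is re-rooted before candidate enumeration. Split
#'   support itself is unaffected by rooting, but without a declared
#'   outgroup the observed candidate set can contain rooted variants of
#'   one unrooted topology that gene-tree splits cannot tell apart;
#'   rooting candidates on the study outgroup removes that ambiguity.
#' @return A data frame of class `"scenario_ranking"`: `rank`,
#'   `topology` (canonical newick over clade names), `mean_score`,
#'   `n_draws_observed` (draws in which the topology occurred among the
#'   pruned gene trees), and `is_reference` (matches the species tree's
#'   clade-level topology). Ties in score are broken by the canonical
#'   newick string. The per-draw, per-node detail is attached as
#'   attribute `"per_node"`.
#' @export
rank_scenarios <- function(species_tree, gene_trees, cm, n_draws, seed,
                           top_n = 12L, mode = c("observed", "consensus"),
                           outgroup = NULL) {
  mode <- match.arg(mode)
  if (!is.null(outgroup) &&
      !outgroup %in% c(names(cm$clades), cm$fixed)) {
    stop("outgroup must be a clade name or a fixed taxon of the clade map")
  }
  gene_trees <- as_tree_list(gene_trees)
  draws <- draw_representatives(cm, n_draws, seed)
  required_nodes <- cm$k - 1L

  pruned_sets <- vector("list", n_draws)
  cand_sets <- vector("list", n_draws)
  for (d in seq_len(n_draws)) {
    reps <- draws[[d]]
    pruned_sets[[d]] <- lapply(gene_trees, function(g) {
      keep <- intersect(g$tip.label, reps)
      if (length(keep) < 3L) return(NULL)
      pg <- prune_to_taxa(g, keep)
      pg$tip.label <- names(reps)[match(pg$tip.label, reps)]
      if (!is.null(outgroup) && outgroup %in% pg$tip.label &&
          length(pg$tip.label) >= 3L) {
        pg <- root_on_outgroup(pg, outgroup)
      }
      pg
    })
    pruned_sets[[d]] <-
      pruned_sets[[d]][!vapply(pruned_sets[[d]], is.null, logical(1))]
    full <- pruned_sets[[d]][vapply(pruned_sets[[d]], function(g)
      length(g$tip.label) == cm$k, NA)]
    cand_sets[[d]] <- withCallingHandlers(
      enumerate_candidates(full, required_nodes, mode = mode),
      warning = function(w) invokeRestart("muffleWarning"))
  }
  candidates <- list()
  for (d in seq_len(n_draws)) {
    new <- setdiff(names(cand_sets[[d]]), names(candidates))
    candidates <- c(candidates, cand_sets[[d]][new])
  }
  if (!length(candidates)) {
    warning("no candidate topology in any draw")
    return(empty_ranking())
  }
  candidates <- candidates[order(names(candidates))]

  score_mat <- matrix(NA_real_, length(candidates), n_draws,
                      dimnames = list(names(candidates), NULL))
  per_node <- vector("list", length(candidates))
  names(per_node) <- names(candidates)
  for (ci in seq_along(candidates)) {
    for (d in seq_len(n_draws)) {
      sc <- score_topology(candidates[[ci]], pruned_sets[[d]])
      score_mat[ci, d] <- sc$score
      per_node[[ci]] <- c(per_node[[ci]], list(sc$per_node))
    }
  }
  mean_score <- rowMeans(score_mat)
  observed_in <- vapply(names(candidates), function(key) {
    sum(vapply(cand_sets, function(cs) key %in% names(cs), NA))
  }, integer(1))

  ref_key <- NA_character_
  if (!is.null(species_tree)) {
    ref <- clade_level_tree(species_tree, cm)
    if (!is.null(ref)) ref_key <- canonical_topology(ref)
  }
  ord <- order(-mean_score, names(candidates))
  out <- data.frame(
    rank = seq_along(ord),
    topology = names(candidates)[ord],
    mean_score = mean_score[ord],
    n_draws_observed = observed_in[ord],
    is_reference = !is.na(ref_key) & names(candidates)[ord] == ref_key,
    stringsAsFactors = FALSE, row.names = NULL
  )
  out <- utils::head(out, top_n)
  attr(out, "per_node") <- per_node[out$topology]
  attr(out, "scores_by_draw") <- score_mat[out$topology, , drop = FALSE]
  class(out) <- c("scenario_ranking", class(out))
  out
}

empty_ranking <- function() {
  out <- data.frame(rank = integer(0), topology = character(0),
                    mean_score = numeric(0), n_draws_observed = integer(0),
                    is_reference = logical(0), stringsAsFactors = FALSE)
  class(out) <- c("scenario_ranking", class(out))
  out
}

#' Clade-level reduction of a species tree
#'
#' Prunes the species tree to one (arbitrary) member per clade plus the
#' fixed taxa and relabels representatives with their clade names. When
#' the map's clades are monophyletic in the species tree the result
#' does not depend on which member is chosen.
#'
#' @param species_tree Rooted `"phylo"`.
#' @param cm A [clade_map()].
#' @return A `"phylo"` on clade names and fixed taxa, or `NULL` when
#'   some clade has no member in the tree.
#' @export
clade_level_tree <- function(species_tree, cm) {
  reps <- vapply(cm$clades, function(m) {
    hit <- intersect(m, species_tree$tip.label)
    if (length(hit)) hit[1L] else NA_character_
  }, "")
  if (anyNA(reps)) return(NULL)
  reps <- c(reps, stats::setNames(cm$fixed, cm$fixed))
  tr <- prune_to_taxa(species_tree, reps)
  tr$tip.label <- names(reps)[match(tr$tip.label, reps)]
  tr$edge.length <- NULL
  tr$node.label <- NULL
  tr
}

# Evaluate an expression under a temporary RNG state. The seed is
# forced first so that a randomly drawn seed advances the caller's RNG.
with_seed <- function(seed, expr) {
  force(seed)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
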