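# Independent oracles used across the suite. These deliberately take
# different routes from the package internals (ape::prop.part clades,
# unordered label-set pairs, direct enumeration) so agreement is
# informative.

# All non-root clades of a rooted tree as label sets, in species-tree
# node order (node ntip+2, ntip+3, ...).
oracle_clades <- function(tree) {
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  lapply(pp[-1], function(idx) sort(labs[idx]))
}

# Split as an unordered pair of sorted label vectors.
oracle_split <- function(a, b) {
  a <- sort(a); b <- sort(b)
  if (paste(a, collapse = "\r") <= paste(b, collapse = "\r")) list(a, b)
  else list(b, a)
}

oracle_split_eq <- function(s1, s2) {
  identical(s1[[1]], s2[[1]]) && identical(s1[[2]], s2[[2]])
}

oracle_conflict <- function(s1, s2) {
  length(intersect(s1[[1]], s2[[1]])) > 0 &&
    length(intersect(s1[[1]], s2[[2]])) > 0 &&
    length(intersect(s1[[2]], s2[[1]])) > 0 &&
    length(intersect(s1[[2]], s2[[2]])) > 0
}

# All splits of a tree restricted to `taxa`, dropping trivial results.
oracle_splits_restricted <- function(tree, taxa = tree$tip.label) {
  out <- list()
  for (cl in oracle_clades(tree)) {
    a <- intersect(cl, taxa)
    b <- intersect(setdiff(tree$tip.label, cl), taxa)
    if (length(a) >= 1 && length(b) >= 1 && length(a) + length(b) >= 3) {
      s <- oracle_split(a, b)
      dup <- any(vapply(out, oracle_split_eq, NA, s))
      if (!dup) out <- c(out, list(s))
    }
  }
  out
}

# Brute-force per-node concordance: for each non-root species-tree
# clade, classify every gene tree by pairwise split comparison.
oracle_concordance <- function(species_tree, gene_trees) {
  sp_tips <- species_tree$tip.label
  clades <- oracle_clades(species_tree)
  t(vapply(clades, function(cl) {
    s_full <- oracle_split(cl, setdiff(sp_tips, cl))
    counts <- c(concordant = 0, conflicting = 0, uninformative = 0)
    for (g in gene_trees) {
      a <- intersect(s_full[[1]], g$tip.label)
      b <- intersect(s_full[[2]], g$tip.label)
      if (length(a) < 1 || length(b) < 1 || length(a) + length(b) < 3) {
        counts["uninformative"] <- counts["uninformative"] + 1
        next
      }
      r <- oracle_split(a, b)
      u <- c(a, b)
      gsplits <- oracle_splits_restricted(g, u)
      if (any(vapply(gsplits, oracle_split_eq, NA, r))) {
        counts["concordant"] <- counts["concordant"] + 1
      } else if (any(vapply(gsplits, oracle_conflict, NA, r))) {
        counts["conflicting"] <- counts["conflicting"] + 1
      } else {
        counts["uninformative"] <- counts["uninformative"] + 1
      }
    }
    counts
  }, c(concordant = 0, conflicting = 0, uninformative = 0)))
}

# Exhaustive enumeration of rooted binary topologies by recursive tip
# insertion; returns the set of canonical strings.
enumerate_rooted_topologies <- function(labels) {
  insert_all <- function(t, x) {
    res <- list(list(t, x))
    if (is.list(t)) {
      for (i in 1:2) {
        for (s in insert_all(t[[i]], x)) {
          t2 <- t
          t2[[i]] <- s
          res <- c(res, list(t2))
        }
      }
    }
    res
  }
  canon <- function(t) {
    if (!is.list(t)) return(t)
    k <- sort(c(canon(t[[1]]), canon(t[[2]])))
    paste0("(", k[1], ",", k[2], ")")
  }
  trees <- list(labels[1])
  for (x in labels[-1]) {
    trees <- unlist(lapply(trees, insert_all, x), recursive = FALSE)
  }
  unique(vapply(trees, canon, ""))
}

# Grid-search oracle for the replicated fraction: same objective family
# (log-scale residuals), located by brute force only.
oracle_replicated_fraction <- function(peaks, step = 1e-4) {
  x <- 2^(seq_along(peaks) - 1) - 1
  lf <- log(peaks)
  grid <- seq(step, 1, by = step)
  sse <- vapply(grid, function(p) {
    d <- lf - log1p(x * p)
    sum((d - mean(d))^2)
  }, 0)
  grid[which.min(sse)]
}

# Random tree with integer bootstrap-like supports on internal nodes.
random_supported_tree <- function(n) {
  tr <- ape::rtree(n)
  tr$node.label <- c("", as.character(sample(0:100, tr$Nnode - 1, TRUE)))
  tr
}

# A cherry-classification helper for rooted triplets: which pair
# coalesced first (tips 1:3, root node 4, cherry node 5).
triplet_pair <- function(tr) {
  inner <- tr$edge[tr$edge[, 1] == 5 & tr$edge[, 2] <= 3, 2]
  paste(sort(tr$tip.label[inner]), collapse = "")
}
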