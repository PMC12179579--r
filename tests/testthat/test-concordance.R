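make_genes <- function(txts) lapply(txts, parse_newick)

test_that("node_concordance matches hand-computed counts on the toy case", {
  sp <- parse_newick("((A,B),(C,D));")
  gt <- make_genes(c("((A,B),(C,D));", "((A,B),(C,D));",
                     "((A,C),(B,D));", "((A,B),C);"))
  nc <- node_concordance(sp, gt)
  row <- nc[nc$split == "A,B | C,D" & !is.na(nc$split), ][1, ]
  expect_equal(row$concordant, 3L)
  expect_equal(row$conflicting, 1L)
  expect_equal(row$uninformative, 0L)
  expect_equal(row$top_alt_split, "A,C | B,D")
  expect_equal(row$top_alt_count, 1L)
})

test_that("identical gene trees are concordant everywhere", {
  sp <- parse_newick("(((A,B),(C,D)),(E,F));")
  gt <- rep(list(sp), 50)
  nc <- node_concordance(sp, gt)
  ok <- !is.na(nc$concordant)
  expect_true(all(nc$concordant[ok] == 50L))
  expect_true(all(nc$conflicting[ok] == 0L))
})

test_that("gene trees missing one side of a split are uninformative there", {
  sp <- parse_newick("((A,B),(C,D));")
  gt <- make_genes("(A,(B,E));")  # E not allowed: tip not in species tree
  expect_error(node_concordance(sp, gt), "E")
  gt2 <- make_genes("((A,B),X);")
  sp2 <- parse_newick("(((A,B),(C,D)),X);")
  nc <- node_concordance(sp2, gt2)
  cd <- nc[!is.na(nc$split) & nc$split == "A,B,X | C,D", ]
  expect_equal(cd$uninformative, 1L)  # C and D both absent
})

test_that("partition law and single-increment monotonicity hold", {
  set.seed(31)
  for (i in 1:30) {
    sp <- ape::rtree(sample(5:8, 1))
    genes <- lapply(1:6, function(j) {
      sub <- sample(sp$tip.label, sample(4:length(sp$tip.label), 1))
      ape::rtree(length(sub), tip.label = sample(sub))
    })
    nc <- node_concordance(sp, genes)
    ok <- !is.na(nc$concordant)
    tot <- nc$concordant[ok] + nc$conflicting[ok] + nc$uninformative[ok]
    expect_true(all(tot == length(genes)))

    # adding one gene increments exactly one category per node
    extra <- ape::rtree(length(sp$tip.label), tip.label = sample(sp$tip.label))
    nc2 <- node_concordance(sp, c(genes, list(extra)))
    d <- cbind(nc2$concordant - nc$concordant,
               nc2$conflicting - nc$conflicting,
               nc2$uninformative - nc$uninformative)[ok, , drop = FALSE]
    expect_true(all(rowSums(d) == 1L))
    expect_true(all(d %in% c(0L, 1L)))
  }
})

test_that("concordance agrees exactly with the brute-force oracle", {
  set.seed(32)
  for (i in 1:60) {
    n <- sample(4:8, 1)
    sp <- ape::rtree(n)
    genes <- lapply(1:8, function(j) {
      m <- sample(3:n, 1)
      g <- ape::rtree(m, tip.label = sample(sp$tip.label, m))
      if (stats::runif(1) < 0.3 && g$Nnode > 2) {
        g$node.label <- c("", sample(0:100, g$Nnode - 1, TRUE))
        g <- collapse_low_support(g, 50)
      }
      g
    })
    nc <- node_concordance(sp, genes)
    orc <- oracle_concordance(sp, genes)
    ok <- !is.na(nc$concordant)
    expect_equal(unname(nc$concordant[ok]), unname(orc[, "concordant"]))
    expect_equal(unname(nc$conflicting[ok]), unname(orc[, "conflicting"]))
    expect_equal(unname(nc$uninformative[ok]), unname(orc[, "uninformative"]))
  }
})

test_that("pie fractions sum to one and match the headline arithmetic", {
  nc <- list(concordant = 387L, conflicting = 239L, uninformative = 4L,
             top_alt_count = 100L)
  f <- pie_fractions(nc)
  expect_equal(sum(f), 1, tolerance = 1e-12)
  expect_equal(unname(f), c(387, 100, 139, 4) / 630, tolerance = 1e-12)
  expect_equal(unname(round(f, 4)), c(0.6143, 0.1587, 0.2206, 0.0063))
  expect_error(pie_fractions(list(concordant = 0L, conflicting = 0L,
                                  uninformative = 0L, top_alt_count = 0L)),
               "no gene trees")
})

test_that("removing a rogue taxon restores concordance at both homes", {
  sp <- parse_newick("((X,(A,B)),((C,D),O));")
  g1 <- parse_newick("(((A,X),B),((C,D),O));")  # X breaks {A,B}
  g2 <- parse_newick("((A,B),(((C,X),D),O));")  # X breaks {C,D}
  genes <- c(rep(list(g1), 10), rep(list(g2), 10))
  jk <- taxon_jackknife(sp, genes, list("X"))[[1]]
  ab <- jk[!is.na(jk$split) & jk$split == "A,B | C,D,O,X", ]
  cd <- jk[!is.na(jk$split) & jk$split == "A,B,O,X | C,D", ]
  expect_equal(ab$concordant_before, 10L)
  expect_equal(cd$concordant_before, 10L)
  expect_equal(ab$concordant_after, 20L)
  expect_equal(cd$concordant_after, 20L)
  expect_equal(ab$delta_concordant, 10L)
})

test_that("jackknife identities: empty removal and absent taxon", {
  sp <- parse_newick("(((A,B),(C,D)),E);")
  genes <- make_genes(c("((A,B),(C,D));", "((A,C),(B,D));"))
  jk <- taxon_jackknife(sp, genes, list(character(0), "E"))
  expect_true(all(jk[[1]]$delta_concordant == 0L, na.rm = TRUE))
  # E occurs in no gene tree: removing it changes nothing
  expect_true(all(jk[[2]]$delta_concordant == 0L, na.rm = TRUE))
  expect_error(taxon_jackknife(sp, genes, list(sp$tip.label)), "every taxon")
})

test_that("jackknife after-counts equal a fresh recount on pruned trees", {
  set.seed(33)
  for (i in 1:20) {
    sp <- ape::rtree(7)
    genes <- lapply(1:5, function(j)
      ape::rtree(7, tip.label = sample(sp$tip.label)))
    rem <- sample(sp$tip.label, 2)
    jk <- taxon_jackknife(sp, genes, list(rem))[[1]]
    sp2 <- prune_to_taxa(sp, setdiff(sp$tip.label, rem))
    genes2 <- lapply(genes, function(g)
      prune_to_taxa(g, setdiff(g$tip.label, rem)))
    fresh <- node_concordance(sp2, genes2)
    # every after-row must exist verbatim in the fresh recount
    ok <- !is.na(jk$concordant_after)
    for (r in which(ok)) {
      hit <- fresh[!is.na(fresh$concordant) &
                     fresh$concordant == jk$concordant_after[r] &
                     fresh$conflicting == jk$conflicting_after[r], ]
      expect_gt(nrow(hit), 0L)
    }
    # after-counts must sum to the pruned gene count
    tot <- jk$concordant_after[ok] + jk$conflicting_after[ok] +
      jk$uninformative_after[ok]
    expect_true(all(tot == length(genes2)))
  }
})
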