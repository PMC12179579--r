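test_that("pgls with lambda 0 reduces exactly to OLS, as does any
           lambda on a star tree", {
  set.seed(81)
  tr <- ape::rcoal(40)
  y <- stats::setNames(rnorm(40), tr$tip.label)
  x <- stats::setNames(rnorm(40), tr$tip.label)
  f <- pgls(tr, y, x, lambda = 0)
  o <- stats::lm(y ~ x)
  expect_equal(f$slope, unname(coef(o)[2]), tolerance = 1e-10)
  expect_equal(f$intercept, unname(coef(o)[1]), tolerance = 1e-10)
  expect_equal(f$p_value, summary(o)$coefficients[2, 4], tolerance = 1e-10)
  expect_equal(f$explained_variance_pct, 100 * summary(o)$r.squared,
               tolerance = 1e-8)

  star <- ape::stree(30, type = "star")
  star$edge.length <- rep(1, nrow(star$edge))
  ys <- stats::setNames(rnorm(30), star$tip.label)
  xs <- stats::setNames(rnorm(30), star$tip.label)
  fs <- pgls(star, ys, xs, lambda = 1)
  os <- stats::lm(ys ~ xs)
  expect_equal(fs$slope, unname(coef(os)[2]), tolerance = 1e-10)
})

test_that("pgls recovers a known slope under Brownian noise", {
  set.seed(82)
  tr <- ape::rcoal(120)
  hits <- 0
  for (i in 1:20) {
    x <- simulate_bm_traits(tr, sigma2 = 1, seed = 1000 + i)
    noise <- simulate_bm_traits(tr, sigma2 = 0.01, seed = 2000 + i)
    y <- 2 * x + noise
    f <- pgls(tr, y, x, lambda = 1)
    if (f$slope > 1.9 && f$slope < 2.1) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("lambda likelihood surface is maximized at the ML estimate
           and cross-checks against an independent implementation", {
  skip_if_not_installed("phytools")
  set.seed(83)
  tr <- ape::rcoal(80)
  y <- simulate_bm_traits(tr, sigma2 = 1, lambda = 0.7, seed = 5)
  pl <- pagel_lambda_ml(tr, y)
  C <- ape::vcv.phylo(tr); d <- diag(C)
  ll <- function(lam) {
    Cl <- lam * C; diag(Cl) <- d
    endophylo:::gls_loglik(unname(y), matrix(1, 80, 1), Cl)$loglik
  }
  for (l0 in c(0, 0.5, 1)) expect_gte(pl$loglik, ll(l0) - 1e-6)
  ps <- phytools::phylosig(tr, y, method = "lambda")
  expect_equal(pl$lambda, ps$lambda, tolerance = 1e-3)
  expect_equal(pl$loglik, ps$logL, tolerance = 1e-4)

  # white noise: lambda near zero, CI lower bound at 0
  wn <- stats::setNames(rnorm(80), tr$tip.label)
  expect_lt(pagel_lambda_ml(tr, wn)$lambda, 0.2)
  expect_error(pagel_lambda_ml(tr, stats::setNames(rep(1, 80),
                                                   tr$tip.label)),
               "zero variance")
})

test_that("lambda is unidentifiable on a star phylogeny", {
  star <- ape::stree(30, type = "star")
  star$edge.length <- rep(1, nrow(star$edge))
  y <- stats::setNames(rnorm(30), star$tip.label)
  pl <- pagel_lambda_ml(star, y)
  expect_equal(pl$ci[1], 0, tolerance = 1e-6)
  expect_true(is.na(pl$ci[2]))
})

test_that("uncertainty replicates collapse to the plain fit at zero
           width and are seed-reproducible", {
  set.seed(84)
  tr <- ape::rcoal(30)
  y <- simulate_bm_traits(tr, seed = 6)
  x <- simulate_bm_traits(tr, seed = 7)
  f <- pgls(tr, y, x, lambda = 1)
  u0 <- pgls_with_uncertainty(tr, y, lower = x, upper = x, n_intra = 10,
                              seed = 9, lambda = 1)
  expect_true(all(abs(u0$p_values - f$p_value) < 1e-12))

  lo <- x - 0.5; hi <- x + 0.5
  u1 <- pgls_with_uncertainty(tr, y, lo, hi, n_intra = 25, seed = 9,
                              lambda = 1)
  u2 <- pgls_with_uncertainty(tr, y, lo, hi, n_intra = 25, seed = 9,
                              lambda = 1)
  expect_identical(u1$p_values, u2$p_values)
  expect_equal(u1$p_median, stats::median(u1$p_values))
  expect_match(u1$summary, "\\(.*-.*\\)")

  # widening the bounds widens the p envelope under common random numbers
  u3 <- pgls_with_uncertainty(tr, y, x - 1, x + 1, n_intra = 25, seed = 9,
                              lambda = 1)
  expect_lte(u3$p_range[1], u1$p_range[1])
  expect_error(pgls_with_uncertainty(tr, y, hi, lo, 5, 1), "exceeds")
})

test_that("phylogenetic ANOVA separates groups and respects the
           smoothing floor", {
  star <- ape::stree(20, type = "star")
  star$edge.length <- rep(1, nrow(star$edge))
  y <- stats::setNames(rep(c(0, 10), each = 10), star$tip.label)
  y <- y + rnorm(20, 0, 0.01)
  g <- stats::setNames(rep(c("a", "b"), each = 10), star$tip.label)
  pa <- phylo_anova(star, y, g, n_sim = 99, seed = 11)
  expect_gt(pa$F, 100)
  expect_lt(pa$p_standard, 1e-10)
  expect_equal(pa$p_phylo, 1 / 100)  # floor 1/(n_sim + 1)
  expect_equal(pa$df1, 1L)
  expect_equal(pa$df2, 18L)
  expect_error(phylo_anova(star, y, stats::setNames(rep("a", 20),
                                                    star$tip.label), 10, 1),
               "two groups")
})

test_that("independent contrasts give n-1 contrasts and a null
           correlation for independent traits", {
  set.seed(85)
  tr <- ape::rcoal(200)
  x <- simulate_bm_traits(tr, seed = 21)
  y <- simulate_bm_traits(tr, seed = 22)
  pc <- pic_correlation(tr, x, y)
  expect_equal(pc$n_contrasts, 199L)
  expect_lt(abs(pc$correlation), 3 / sqrt(199))
  # identical traits correlate perfectly
  z <- x + 0.01 * y
  expect_gt(pic_correlation(tr, x, z)$correlation, 0.99)
  tr2 <- tr; tr2$edge.length <- NULL
  expect_error(pic_correlation(tr2, x, y), "branch lengths")
})

test_that("ancestral states match a brute-force GLS solve and an
           independent implementation", {
  skip_if_not_installed("phytools")
  set.seed(86)
  tr <- ape::rcoal(6)
  y <- simulate_bm_traits(tr, seed = 31)
  a <- ancestral_states_bm(tr, y)
  # brute force from the joint covariance
  Cf <- endophylo:::full_vcv(tr)
  Ctt <- Cf[1:6, 1:6]; Cnt <- Cf[7:11, 1:6]
  Ci <- solve(Ctt)
  mu <- drop(colSums(Ci) %*% y / sum(Ci))
  brute <- drop(mu + Cnt %*% Ci %*% (y - mu))
  expect_equal(unname(a$states), brute, tolerance = 1e-8)
  expect_equal(unname(a$states[1]), a$phylo_mean)
  fa <- phytools::fastAnc(tr, y)
  expect_equal(unname(a$states), unname(c(fa)), tolerance = 1e-6)

  # constant trait: every node at the constant, zero variance signal
  cst <- stats::setNames(rep(3.7, 6), tr$tip.label)
  ac <- ancestral_states_bm(tr, cst)
  expect_true(all(abs(ac$states - 3.7) < 1e-10))
  expect_equal(ac$sigma2, 0, tolerance = 1e-12)

  # two-tip symmetry
  t2 <- parse_newick("(A:1,B:1);")
  a2 <- ancestral_states_bm(t2, c(A = 0, B = 10))
  expect_equal(unname(a2$states), 5)
})

test_that("significant-change detection flags jumps but not constants", {
  set.seed(87)
  tr <- ape::rcoal(60)
  cst <- stats::setNames(rep(1, 60), tr$tip.label)
  expect_equal(sum(significant_changes(tr, cst)$significant), 0L)

  hits <- 0
  for (i in 1:25) {
    y <- simulate_bm_traits(tr, sigma2 = 1, seed = 500 + i)
    internal <- which(tr$edge[, 2] > 61)
    e <- internal[which.max(tr$edge.length[internal])]
    clade_tips <- ape::extract.clade(tr, tr$edge[e, 2])$tip.label
    y[clade_tips] <- y[clade_tips] + 10 * sqrt(tr$edge.length[e])
    if (significant_changes(tr, y)$significant[e]) hits <- hits + 1
  }
  expect_gte(hits, 24)
})
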