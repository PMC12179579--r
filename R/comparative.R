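#' Phylogenetic (Brownian) covariance with Pagel's lambda transform
#'
#' The Brownian-motion covariance of tip values is the matrix of shared
#' root-to-tip path lengths. Pagel's lambda multiplies the off-diagonal
#' entries by lambda in \[0, 1\], interpolating between a star phylogeny
#' (lambda = 0, independent tips) and pure Brownian motion (lambda = 1).
#'
#' @param tree A `"phylo"` with branch lengths.
#' @param lambda Signal parameter in \[0, 1\].
#' @return Covariance matrix ordered as `tree$tip.label`.
#' @export
phylo_vcv <- function(tree, lambda = 1) {
  stopifnot(lambda >= 0, lambda <= 1)
  C <- ape::vcv.phylo(tree)
  if (lambda != 1) {
    d <- diag(C)
    C <- lambda * C
    diag(C) <- d
  }
  C
}

# Match a named data vector to the tree's tips, with errors on mismatch.
match_to_tips <- function(tree, x, what = "trait") {
  if (is.null(names(x))) {
    if (length(x) != length(tree$tip.label)) {
      stop(what, " must be named by tip label or match the tip count")
    }
    names(x) <- tree$tip.label
    return(x)
  }
  miss <- setdiff(tree$tip.label, names(x))
  if (length(miss)) {
    stop(what, " missing for tip(s): ", paste(sQuote(miss), collapse = ", "))
  }
  x[tree$tip.label]
}

# Profile log-likelihood machinery for the lambda-transformed BM model
# with design matrix X (GLS mean). Returns ML beta, sigma2, loglik.
gls_loglik <- function(y, X, C) {
  n <- length(y)
  L <- chol(C)
  w <- backsolve(L, cbind(y, X), transpose = TRUE)
  yw <- w[, 1L]
  Xw <- w[, -1L, drop = FALSE]
  fit <- stats::lm.fit(Xw, yw)
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / n
  ll <- -n / 2 * (log(2 * pi * sigma2) + 1) - sum(log(diag(L)))
  list(beta = fit$coefficients, sigma2 = sigma2, loglik = ll, rss = rss,
       L = L, Xw = Xw, yw = yw)
}

#' Maximum-likelihood Pagel's lambda with likelihood-ratio CI
#'
#' Maximizes the Brownian-motion likelihood of a continuous trait over
#' the lambda transform on \[0, 1\] (grid pre-scan followed by bounded
#' optimization) and reports a 95 percent confidence interval from the
#' chi-square(1) likelihood-ratio cutoff. When lambda sits at the
#' boundary 1 and the cutoff cannot exclude it, the upper bound is
#' reported as `NA`, matching the conventional "CI = x-NA" notation.
#'
#' @param tree A `"phylo"` with positive branch lengths (>= 4 tips).
#' @param trait Named numeric vector of tip values.
#' @return A list of class `"pagel_lambda"`: `lambda`, `ci` (length-2,
#'   possibly `NA` at an unexcludable boundary), `loglik`, `loglik0`
#'   (lambda = 0), and `p_value` of the LR test against lambda = 0.
#' @export
pagel_lambda_ml <- function(tree, trait) {
  if (length(tree$tip.label) < 4L) stop("need at least 4 tips")
  y <- match_to_tips(tree, trait)
  if (stats::var(y) == 0) stop("trait has zero variance")
  C <- ape::vcv.phylo(tree)
  d <- diag(C)
  X <- matrix(1, length(y), 1L)
  ll_of <- function(lam) {
    Cl <- lam * C
    diag(Cl) <- d
    gls_loglik(y, X, Cl)$loglik
  }
  grid <- seq(0, 1, by = 0.05)
  lg <- vapply(grid, ll_of, 0)
  i <- which.max(lg)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(ll_of, c(lo, hi), maximum = TRUE, tol = 1e-6)
  lambda <- opt$maximum
  llmax <- opt$objective
  # snap to boundaries when they are at least as good
  if (ll_of(1) >= llmax - 1e-8) { lambda <- 1; llmax <- ll_of(1) }
  if (ll_of(0) >= llmax - 1e-8) { lambda <- 0; llmax <- ll_of(0) }
  cutoff <- llmax - stats::qchisq(0.95, 1) / 2
  ci_lo <- if (ll_of(0) >= cutoff) 0 else
    stats::uniroot(function(l) ll_of(l) - cutoff, c(0, lambda))$root
  ci_hi <- if (ll_of(1) >= cutoff) NA_real_ else
    stats::uniroot(function(l) ll_of(l) - cutoff, c(lambda, 1))$root
  ll0 <- ll_of(0)
  structure(list(lambda = lambda, ci = c(ci_lo, ci_hi), loglik = llmax,
                 loglik0 = ll0,
                 p_value = stats::pchisq(2 * (llmax - ll0), 1,
                                         lower.tail = FALSE)),
            class = "pagel_lambda")
}

#' Phylogenetic generalized least squares regression
#'
#' Fits `response ~ predictor` by GLS under the lambda-transformed
#' Brownian covariance. `lambda` may be a fixed value in \[0, 1\]
#' (lambda = 0 reduces exactly to ordinary least squares) or `"ML"`,
#' in which case it is profiled out by maximum likelihood jointly with
#' the regression.
#'
#' @param tree A `"phylo"` with branch lengths.
#' @param response,predictor Named numeric tip vectors.
#' @param lambda `"ML"` or a fixed value in \[0, 1\].
#' @return A list of class `"pgls_fit"`: `slope`, `intercept`,
#'   `p_value` (t test on the slope), `explained_variance_pct`
#'   (GLS R-squared on the whitened scale, in percent), `lambda`, `n`,
#'   `sigma2`, `loglik`, and `se_slope`.
#' @export
pgls <- function(tree, response, predictor, lambda = "ML") {
  y <- match_to_tips(tree, response, "response")
  x <- match_to_tips(tree, predictor, "predictor")
  keep <- !is.na(y) & !is.na(x)
  if (!all(keep)) {
    tree <- prune_to_taxa(tree, names(y)[keep])
    y <- y[tree$tip.label]
    x <- x[tree$tip.label]
  }
  n <- length(y)
  if (stats::var(x) == 0) stop("singular design: constant predictor")
  C <- ape::vcv.phylo(tree)
  d <- diag(C)
  X <- cbind(`(Intercept)` = 1, x = x)
  fit_at <- function(lam) {
    Cl <- lam * C
    diag(Cl) <- d
    gls_loglik(y, X, Cl)
  }
  if (identical(lambda, "ML")) {
    grid <- seq(0, 1, by = 0.05)
    lg <- vapply(grid, function(l) fit_at(l)$loglik, 0)
    i <- which.max(lg)
    opt <- stats::optimize(function(l) fit_at(l)$loglik,
                           c(grid[max(1L, i - 1L)],
                             grid[min(length(grid), i + 1L)]),
                           maximum = TRUE, tol = 1e-6)
    lambda <- opt$maximum
    if (fit_at(1)$loglik >= opt$objective - 1e-8) lambda <- 1
    if (fit_at(0)$loglik >= opt$objective - 1e-8) lambda <- 0
  }
  f <- fit_at(lambda)
  p <- ncol(X)
  s2_resid <- f$rss / (n - p)
  XtX_inv <- chol2inv(chol(crossprod(f$Xw)))
  se <- sqrt(s2_resid * diag(XtX_inv))
  tstat <- f$beta / se
  pval <- 2 * stats::pt(abs(tstat), df = n - p, lower.tail = FALSE)
  # whitened-scale R^2 against the GLS intercept-only fit
  fit0 <- stats::lm.fit(f$Xw[, 1L, drop = FALSE], f$yw)
  tss <- sum(fit0$residuals^2)
  structure(list(slope = unname(f$beta[2L]), intercept = unname(f$beta[1L]),
                 p_value = unname(pval[2L]),
                 explained_variance_pct = 100 * (1 - f$rss / tss),
                 lambda = lambda, n = n, sigma2 = f$sigma2,
                 loglik = f$loglik, se_slope = unname(se[2L])),
            class = "pgls_fit")
}

#' PGLS with interval uncertainty on the predictor
#'
#' Propagates per-taxon predictor uncertainty through PGLS in the style
#' of interval sensitivity analyses: each replicate draws every taxon's
#' predictor value uniformly between its lower and upper bound (e.g.
#' the 47.5 and 52.5 percentiles of the environmental layer over the
#' taxon's range) and refits. Replicates are summarized as the median p
#' with the min-max envelope, printed `"p (min-max)"`.
#'
#' @param tree A `"phylo"` with branch lengths.
#' @param response Named numeric tip vector.
#' @param lower,upper Named per-taxon predictor bounds (lower <= upper).
#' @param n_intra Number of replicates (the study convention is 1000).
#' @param seed Integer RNG seed.
#' @param lambda Passed to [pgls()] (default `"ML"`).
#' @return A list of class `"pgls_uncertainty"`: `p_values` (length
#'   `n_intra`), `p_median`, `p_range`, `slopes`, `seed`, and
#'   `summary` (the formatted string).
#' @export
pgls_with_uncertainty <- function(tree, response, lower, upper, n_intra,
                                  seed, lambda = "ML") {
  lo <- match_to_tips(tree, lower, "lower bound")
  hi <- match_to_tips(tree, upper, "upper bound")
  if (any(lo > hi)) stop("lower bound exceeds upper bound for some taxon")
  n <- length(lo)
  res <- with_seed(seed, {
    lapply(seq_len(n_intra), function(i) {
      u <- stats::runif(n)
      x <- lo + u * (hi - lo)
      names(x) <- names(lo)
      fit <- pgls(tree, response, x, lambda = lambda)
      c(p = fit$p_value, slope = fit$slope)
    })
  })
  p <- vapply(res, `[[`, 0, "p")
  s <- vapply(res, `[[`, 0, "slope")
  structure(list(p_values = p, p_median = stats::median(p),
                 p_range = range(p), slopes = s, seed = seed,
                 summary = sprintf("%.3g (%.3g-%.3g)", stats::median(p),
                                   min(p), max(p))),
            class = "pgls_uncertainty")
}

#' Phylogenetic ANOVA by Brownian simulation
#'
#' The observed statistic is the classical one-way ANOVA F. Its
#' phylogenetic null distribution is obtained by simulating the trait
#' under Brownian motion on the tree (rate and mean estimated from the
#' data by ML) and recomputing F for each simulation; the phylogenetic
#' p-value is the add-one-smoothed exceedance fraction, so its floor is
#' 1/(n_sim + 1).
#'
#' @param tree A `"phylo"` with branch lengths.
#' @param trait Named numeric tip vector.
#' @param groups Named factor/character vector of group labels.
#' @param n_sim Number of Brownian null simulations (default 1000).
#' @param seed Integer RNG seed.
#' @return A list of class `"phylo_anova"`: `F`, `df1`, `df2`,
#'   `p_standard` (classical F test), `p_phylo`, `n_sim`.
#' @export
phylo_anova <- function(tree, trait, groups, n_sim = 1000, seed = 1) {
  y <- match_to_tips(tree, trait)
  g <- factor(match_to_tips(tree, groups, "groups"))
  k <- nlevels(g)
  if (k < 2L) stop("need at least two groups")
  if (any(table(g) < 2L)) stop("every group needs at least two members")
  n <- length(y)
  f_of <- function(v) {
    gm <- tapply(v, g, mean)
    ssb <- sum(table(g) * (gm - mean(v))^2)
    ssw <- sum((v - gm[g])^2)
    (ssb / (k - 1)) / (ssw / (n - k))
  }
  f_obs <- f_of(y)
  C <- ape::vcv.phylo(tree)
  ml <- gls_loglik(y, matrix(1, n, 1L), C)
  mu <- ml$beta[[1L]]
  sig2 <- ml$sigma2
  Lt <- chol(C)
  fsim <- with_seed(seed, {
    Z <- matrix(stats::rnorm(n * n_sim), n, n_sim)
    Y <- mu + sqrt(sig2) * crossprod(Lt, Z)
    apply(Y, 2L, f_of)
  })
  structure(list(F = f_obs, df1 = k - 1L, df2 = n - k,
                 p_standard = stats::pf(f_obs, k - 1, n - k,
                                        lower.tail = FALSE),
                 p_phylo = (1 + sum(fsim >= f_obs)) / (n_sim + 1),
                 n_sim = n_sim),
            class = "phylo_anova")
}

#' Correlation of two traits through phylogenetic independent contrasts
#'
#' Computes Felsenstein's standardized contrasts for both traits
#' (polytomies are resolved arbitrarily with zero-length branches
#' first) and their correlation through the origin, with the p-value of
#' the corresponding no-intercept regression.
#'
#' @param tree A `"phylo"` with branch lengths.
#' @param trait_x,trait_y Named numeric tip vectors.
#' @return A list of class `"pic_cor"`: `correlation`, `p_value`,
#'   `n_contrasts`, and the contrast vectors `pic_x`, `pic_y`.
#' @export
pic_correlation <- function(tree, trait_x, trait_y) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  x <- match_to_tips(tree, trait_x, "trait_x")
  y <- match_to_tips(tree, trait_y, "trait_y")
  if (!is_fully_resolved(tree)) tree <- ape::multi2di(tree)
  cx <- ape::pic(x[tree$tip.label], tree)
  cy <- ape::pic(y[tree$tip.label], tree)
  r <- sum(cx * cy) / sqrt(sum(cx^2) * sum(cy^2))
  fit <- summary(stats::lm(cy ~ cx - 1))
  structure(list(correlation = r,
                 p_value = unname(fit$coefficients[1L, 4L]),
                 n_contrasts = length(cx), pic_x = cx, pic_y = cy),
            class = "pic_cor")
}

# Full (tips + internal nodes) BM covariance: shared path length from
# the root to the most recent common ancestor of each pair.
full_vcv <- function(tree) {
  M <- ape::mrca(tree, full = TRUE)
  d <- ape::node.depth.edgelength(tree)
  matrix(d[M], nrow(M), ncol(M))
}

#' Ancestral state reconstruction under Brownian motion
#'
#' GLS (equivalently ML) estimates of internal-node states, with
#' estimation variances that include the uncertainty of the estimated
#' phylogenetic mean. The root estimate equals the GLS phylogenetic
#' mean.
#'
#' @param tree A `"phylo"` with positive branch lengths.
#' @param trait Named numeric tip vector.
#' @return A list of class `"anc_states"`: `states` and `variances`
#'   (named by ape node number), `sigma2` (ML Brownian rate), and
#'   `phylo_mean`.
#' @export
ancestral_states_bm <- function(tree, trait) {
  y <- match_to_tips(tree, trait)
  ntip <- length(tree$tip.label)
  Cf <- full_vcv(tree)
  tt <- seq_len(ntip)
  nn <- seq.int(ntip + 1L, ntip + tree$Nnode)
  Ctt <- Cf[tt, tt]
  Cnt <- Cf[nn, tt, drop = FALSE]
  Cnn <- Cf[nn, nn, drop = FALSE]
  ones <- rep(1, ntip)
  Ci <- chol2inv(chol(Ctt))
  denom <- sum(Ci)
  mu <- sum(Ci %*% y) / denom
  r <- y - mu
  sig2 <- drop(crossprod(r, Ci %*% r)) / ntip
  A <- Cnt %*% Ci                        # projection weights
  states <- drop(mu + A %*% r)
  base_var <- diag(Cnn) - rowSums(A * Cnt)
  mean_term <- (1 - rowSums(A))^2 / denom
  vars <- sig2 * (base_var + mean_term)
  vars[vars < 0] <- 0                    # numerical guard
  names(states) <- names(vars) <- as.character(nn)
  structure(list(states = states, variances = vars, sigma2 = sig2,
                 phylo_mean = mu),
            class = "anc_states")
}

#' Branch-wise detection of significant trait changes
#'
#' Flags branches along which the reconstructed trait change is larger
#' than Brownian motion can plausibly explain: the change between the
#' endpoint estimates is compared with a normal null whose variance is
#' the Brownian variance accrued along the branch
#' (\eqn{\hat\sigma^2 t}) plus the estimation variances of the two
#' endpoint states. A branch is flagged when |change| exceeds the
#' two-sided (1 - alpha) normal quantile of that null.
#'
#' @param tree A `"phylo"` with positive branch lengths.
#' @param trait Named numeric tip vector.
#' @param alpha Significance level (default 0.05).
#' @return A data frame with one row per edge: `parent`, `child`,
#'   `length`, `change`, `z`, `significant`.
#' @export
significant_changes <- function(tree, trait, alpha = 0.05) {
  asr <- ancestral_states_bm(tree, trait)
  y <- match_to_tips(tree, trait)
  if (stats::var(y) < .Machine$double.eps * max(1, mean(y)^2)) {
    # constant trait: no Brownian variance, nothing to flag
    return(data.frame(parent = tree$edge[, 1L], child = tree$edge[, 2L],
                      length = tree$edge.length,
                      change = 0, z = 0, significant = FALSE))
  }
  ntip <- length(tree$tip.label)
  state_of <- function(v) {
    if (v <= ntip) unname(y[tree$tip.label[v]]) else
      asr$states[[as.character(v)]]
  }
  var_of <- function(v) {
    if (v <= ntip) 0 else asr$variances[[as.character(v)]]
  }
  parent <- tree$edge[, 1L]
  child <- tree$edge[, 2L]
  len <- tree$edge.length
  change <- vapply(seq_along(parent), function(e) {
    state_of(child[e]) - state_of(parent[e])
  }, 0)
  vtot <- asr$sigma2 * len +
    vapply(parent, var_of, 0) + vapply(child, var_of, 0)
  z <- ifelse(vtot > 0, change / sqrt(vtot), 0)
  data.frame(parent = parent, child = child, length = len,
             change = change, z = z,
             significant = abs(z) > stats::qnorm(1 - alpha / 2))
}
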