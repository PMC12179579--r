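#' Construct a flow-cytometry run record
#'
#' Bundles the relative fluorescence peak positions of one accession:
#' the sample peak series (2C nucleus peak first, then successive
#' endoreplicated peaks) under the intercalating stain (propidium
#' iodide, PI — the quantitative, base-neutral stain) and optionally
#' under the AT-preferential stain (DAPI), plus the 2C peak of the
#' internal size standard under each stain and the standard's known
#' genome size and GC content.
#'
#' @param sample_pi Numeric vector of sample peak fluorescences under
#'   PI, strictly increasing; successive peaks must differ by at most
#'   two-fold (the partial-endoreplication constraint).
#' @param standard_pi The standard's 2C peak under PI.
#' @param standard_2c_mbp The standard's 2C genome size in Mbp.
#' @param sample_dapi,standard_dapi Peaks under DAPI (optional; needed
#'   for GC estimation).
#' @param standard_gc Standard GC content in percent (optional).
#' @param id Accession identifier.
#' @return A list of class `"fcm_run"`.
#' @export
fcm_run <- function(sample_pi, standard_pi, standard_2c_mbp,
                    sample_dapi = NULL, standard_dapi = NULL,
                    standard_gc = NULL, id = NA_character_) {
  stopifnot(is.numeric(sample_pi), length(sample_pi) >= 1L)
  if (any(sample_pi <= 0)) stop("fluorescence values must be positive")
  if (is.unsorted(sample_pi, strictly = TRUE)) {
    stop("sample peak series must be strictly increasing")
  }
  if (length(sample_pi) >= 2L) {
    ratio <- sample_pi[-1L] / sample_pi[-length(sample_pi)]
    # two-fold at most in expectation; the slack absorbs peak-position noise
    if (any(ratio > 2.5)) {
      stop("successive peaks differ by more than two-fold; not an ",
           "endoreplication series")
    }
  }
  if (!is.null(standard_pi) && standard_pi <= 0) {
    stop("standard fluorescence must be positive")
  }
  structure(list(id = id, sample_pi = sample_pi,
                 sample_dapi = sample_dapi,
                 standard_pi = standard_pi, standard_dapi = standard_dapi,
                 standard_2c_mbp = standard_2c_mbp,
                 standard_gc = standard_gc),
            class = "fcm_run")
}

#' Genome size from the 2C peak ratio to the internal standard
#'
#' @param run An [fcm_run()].
#' @return Named numeric vector with `gs_2c_mbp` and `gs_1c_mbp`.
#' @details 2C genome size is the sample/standard ratio of 2C PI peaks
#'   times the standard's 2C size; the 1C value is half of it.
#' @examples
#' r <- fcm_run(sample_pi = 200, standard_pi = 400, standard_2c_mbp = 9000)
#' genome_size(r)  # 4500 / 2250
#' @export
genome_size <- function(run) {
  stopifnot(inherits(run, "fcm_run"))
  if (is.null(run$standard_pi) || is.null(run$standard_2c_mbp)) {
    stop("internal standard (PI peak and 2C size) is required")
  }
  gs2 <- run$sample_pi[1L] / run$standard_pi * run$standard_2c_mbp
  c(gs_2c_mbp = gs2, gs_1c_mbp = gs2 / 2)
}

#' Replicated genome fraction P from an endoreplication peak series
#'
#' Under partial endoreplication only a fraction P of the genome is
#' re-replicated in each endocycle, so the expected fluorescence of the
#' peak after r rounds is \eqn{F_r = F_0 (1 + (2^r - 1) P)}. P is
#' estimated by least squares over all peaks on the log scale (the
#' appropriate scale for the multiplicative peak-position noise of flow
#' cytometers), with \eqn{\log F_0} profiled out and P located by a
#' grid scan over (0, 1] refined by bounded optimization. The estimate
#' is exact on noise-free series.
#'
#' @param peaks Numeric vector of PI peak fluorescences (2C first),
#'   length >= 2.
#' @return Estimated P in (0, 1].
#' @examples
#' replicated_fraction(c(100, 150))       # 0.5
#' replicated_fraction(c(100, 200, 400))  # 1
#' @export
replicated_fraction <- function(peaks) {
  if (length(peaks) < 2L) {
    stop("at least two peaks are required to estimate P")
  }
  if (any(peaks <= 0)) stop("fluorescence values must be positive")
  x <- 2^(seq_along(peaks) - 1) - 1
  lf <- log(peaks)
  obj <- function(p) {
    m <- log1p(x * p)
    d <- lf - m
    sum((d - mean(d))^2)
  }
  grid <- seq(0.002, 1, by = 0.002)
  p0 <- grid[which.min(vapply(grid, obj, 0))]
  opt <- stats::optimize(obj, c(max(1e-9, p0 - 0.004), min(1, p0 + 0.004)),
                         tol = 1e-10)
  # candidate set: the refined optimum, the boundary, and the exact
  # closed-form solutions of each consecutive peak pair (these make the
  # estimate exact on noise-free series)
  rho <- peaks[-1L] / peaks[-length(peaks)]
  pairwise <- (rho - 1) / (x[-1L] - rho * x[-length(x)])
  cand <- c(opt$minimum, 1, pairwise)
  cand <- cand[is.finite(cand) & cand > 0 & cand <= 1]
  p <- cand[which.min(vapply(cand, obj, 0))]
  min(max(p, .Machine$double.eps), 1)
}

#' Classify endoreplication type from the replicated fraction
#'
#' Accessions replicating at least 95 percent of the genome are called
#' conventional (CE); the threshold is inclusive on the CE side because
#' it exists to absorb measurement error around complete replication.
#'
#' @param p Replicated fraction in (0, 1].
#' @param threshold Classification threshold (default 0.95).
#' @return `"CE"` or `"PE"` (vectorized over `p`).
#' @export
classify_endoreplication <- function(p, threshold = 0.95) {
  stopifnot(all(p > 0 & p <= 1))
  ifelse(p >= threshold, "CE", "PE")
}

#' GC content from the DAPI/PI dye factor
#'
#' The dye factor DF = DAPI/PI fluorescence of the same 2C peak carries
#' base-composition information: DAPI binds runs of AT while PI is
#' base-neutral. With a binding-site model in which DAPI fluorescence
#' is proportional to the AT fraction raised to the binding length n,
#' the sample AT fraction follows from the standard's by
#' \eqn{AT_s = AT_{std} (DF_s / DF_{std})^{1/n}}, and GC = 100 - AT.
#'
#' @param run An [fcm_run()] with DAPI peaks and a standard GC value.
#' @param binding_length DAPI binding length n (default 4).
#' @return GC content of the sample in percent.
#' @examples
#' r <- fcm_run(sample_pi = 200, sample_dapi = 220,
#'              standard_pi = 400, standard_dapi = 400,
#'              standard_2c_mbp = 9000, standard_gc = 40)
#' gc_content(r)
#' @export
gc_content <- function(run, binding_length = 4) {
  stopifnot(inherits(run, "fcm_run"))
  if (is.null(run$sample_dapi) || is.null(run$standard_dapi) ||
      is.null(run$standard_gc)) {
    stop("DAPI peaks and standard GC are required for GC estimation")
  }
  if (any(c(run$sample_dapi[1L], run$standard_dapi[1L],
            run$sample_pi[1L], run$standard_pi[1L]) <= 0)) {
    stop("fluorescence values must be positive")
  }
  df_s <- run$sample_dapi[1L] / run$sample_pi[1L]
  df_std <- run$standard_dapi[1L] / run$standard_pi[1L]
  at_std <- 100 - run$standard_gc
  at_s <- at_std * (df_s / df_std)^(1 / binding_length)
  100 - at_s
}

#' GC content of the replicated genome fraction
#'
#' After one endocycle a nucleus holds the full genome plus the
#' replicated fraction P, so its bulk GC content is a mass-balance mix
#' of the two. Given the 2C GC content and the GC content measured at
#' the first endoreplicated peak, the GC content of the replicated
#' fraction is \eqn{GC_{rep} = (GC_1 (1 + P) - GC_0) / P}.
#'
#' @param gc_0 GC percent at the 2C peak.
#' @param gc_1 GC percent at the first endoreplicated peak.
#' @param p Replicated fraction in (0, 1].
#' @return GC percent of the replicated fraction. Values outside
#'   (0, 100) indicate a model violation and are returned with a
#'   warning rather than suppressed.
#' @examples
#' infer_fraction_gc(40, 44, 0.5)  # 52
#' @export
infer_fraction_gc <- function(gc_0, gc_1, p) {
  stopifnot(all(p > 0 & p <= 1))
  out <- (gc_1 * (1 + p) - gc_0) / p
  if (any(out <= 0 | out >= 100)) {
    warning("inferred GC of the replicated fraction outside (0, 100); ",
            "mass-balance model violated")
  }
  out
}

#' Derive the full trait record from a flow-cytometry run
#'
#' @param run An [fcm_run()].
#' @param binding_length DAPI binding length for GC estimation.
#' @return A one-row data frame: `id`, `gs_2c_mbp`, `gs_1c_mbp`, `p`,
#'   `endo_type`, `gc_pct` (NA without DAPI data), and
#'   `replicated_gs_mbp` = p * 1C genome size.
#' @export
derive_traits <- function(run, binding_length = 4) {
  gs <- genome_size(run)
  p <- if (length(run$sample_pi) >= 2L) replicated_fraction(run$sample_pi)
       else NA_real_
  gc <- if (!is.null(run$sample_dapi) && !is.null(run$standard_dapi) &&
            !is.null(run$standard_gc))
    gc_content(run, binding_length) else NA_real_
  data.frame(
    id = run$id,
    gs_2c_mbp = unname(gs["gs_2c_mbp"]),
    gs_1c_mbp = unname(gs["gs_1c_mbp"]),
    p = p,
    endo_type = if (is.na(p)) NA_character_ else classify_endoreplication(p),
    gc_pct = gc,
    replicated_gs_mbp = p * unname(gs["gs_1c_mbp"]),
    stringsAsFactors = FALSE
  )
}

#' Range and fold statistics of a trait, optionally by group
#'
#' @param values Numeric trait values (e.g. 1C genome sizes in Mbp or
#'   GC percentages).
#' @param groups Optional grouping factor (e.g. endoreplication type or
#'   genus); when given, statistics are computed per group and for the
#'   pooled data (group `"all"`).
#' @return A data frame with `group`, `n`, `min`, `max`,
#'   `fold` (max/min) and `range` (max - min).
#' @examples
#' summarize_traits(c(289.1, 3849.1))  # fold 13.3
#' @export
summarize_traits <- function(values, groups = NULL) {
  stopifnot(length(values) >= 1L)
  one <- function(v, g) {
    v <- v[!is.na(v)]
    data.frame(group = g, n = length(v), min = min(v), max = max(v),
               fold = max(v) / min(v), range = max(v) - min(v),
               stringsAsFactors = FALSE)
  }
  if (is.null(groups)) return(one(values, "all"))
  parts <- lapply(split(values, groups), function(v) v)
  out <- do.call(rbind, Map(one, parts, names(parts)))
  rbind(one(values, "all"), out)
}
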