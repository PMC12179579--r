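#' Simulate gene trees under the multispecies coalescent
#'
#' Samples gene trees within a species tree whose branch lengths are in
#' coalescent units (2N generations), with one lineage per species.
#' Within every species-tree branch, the j lineages present coalesce at
#' rate j(j-1)/2 per unit time; lineages remaining at the species-tree
#' root coalesce in its (infinite) ancestral branch. For a rooted
#' triplet `((A,B),C)` with internal branch t this yields the classic
#' concordance probability \eqn{1 - (2/3) e^{-t}}.
#'
#' @param species_tree Rooted `"phylo"` with branch lengths in
#'   coalescent units.
#' @param n_genes Number of gene trees.
#' @param seed Integer RNG seed.
#' @return A `"multiPhylo"` of gene trees with branch lengths in
#'   coalescent units.
#' @export
simulate_gene_trees_msc <- function(species_tree, n_genes, seed) {
  stopifnot(inherits(species_tree, "phylo"), n_genes >= 1)
  if (is.null(species_tree$edge.length)) {
    stop("species tree needs branch lengths (coalescent units)")
  }
  ntip <- length(species_tree$tip.label)
  depth <- ape::node.depth.edgelength(species_tree)  # from the root
  parent <- integer(ntip + species_tree$Nnode)
  parent[species_tree$edge[, 2L]] <- species_tree$edge[, 1L]
  children <- vector("list", ntip + species_tree$Nnode)
  for (e in seq_len(nrow(species_tree$edge))) {
    p <- species_tree$edge[e, 1L]
    children[[p]] <- c(children[[p]], species_tree$edge[e, 2L])
  }
  root <- ntip + 1L

  sim_one <- function() {
    # a lineage is list(frag = newick fragment, d = depth of its head)
    coalesce <- function(lin, t_start, t_end) {
      j <- length(lin)
      t <- t_start
      while (j >= 2L) {
        t <- t - stats::rexp(1L, j * (j - 1L) / 2)
        if (t < t_end) break
        pair <- sample.int(j, 2L)
        a <- lin[[pair[1L]]]
        b <- lin[[pair[2L]]]
        merged <- list(
          frag = sprintf("(%s:%.10g,%s:%.10g)", a$frag, a$d - t,
                         b$frag, b$d - t),
          d = t)
        lin <- c(lin[-pair], list(merged))
        j <- j - 1L
      }
      lin
    }
    recurse <- function(v) {
      lin <- if (v <= ntip) {
        list(list(frag = species_tree$tip.label[v], d = depth[v]))
      } else {
        unlist(lapply(children[[v]], recurse), recursive = FALSE)
      }
      t_end <- if (v == root) -Inf else depth[parent[v]]
      coalesce(lin, depth[v], t_end)
    }
    out <- recurse(root)
    paste0(out[[1L]]$frag, ";")
  }
  txt <- with_seed(seed, vapply(seq_len(n_genes), function(i) sim_one(), ""))
  trs <- ape::read.tree(text = paste(txt, collapse = "\n"))
  if (inherits(trs, "phylo")) trs <- structure(list(trs),
                                               class = "multiPhylo")
  trs
}

#' Inject a hybrid-like alternative-topology signal into gene trees
#'
#' Emulates the gene-tree signature of a hybridogenous lineage: in an
#' independently sampled fraction `gamma` of the gene trees, the target
#' clade is pruned and re-attached (a subtree prune and regraft) as
#' sister to an alternative attachment clade, so concordance at the
#' affected node shows two dominant topologies with frequencies about
#' (1 - gamma, gamma). Gene trees in which the target clade is not
#' monophyletic are left untouched (counted in a single warning).
#'
#' @param gene_trees `"multiPhylo"` or list of gene trees with branch
#'   lengths.
#' @param clade Character vector: tips of the clade to move.
#' @param attach_to Character vector: the moved clade is re-attached on
#'   the edge above the most recent common ancestor of these tips.
#' @param gamma Fraction of gene trees carrying the alternative signal.
#' @param seed Integer RNG seed.
#' @return The modified list of gene trees, with attribute `"moved"`
#'   giving the indices actually moved.
#' @export
inject_hybrid_signal <- function(gene_trees, clade, attach_to, gamma, seed) {
  stopifnot(gamma >= 0, gamma <= 1)
  gene_trees <- as_tree_list(gene_trees)
  if (gamma == 0) {
    attr(gene_trees, "moved") <- integer(0)
    return(gene_trees)
  }
  skipped <- 0L
  moved <- integer(0)
  out <- with_seed(seed, {
    pick <- stats::runif(length(gene_trees)) < gamma
    lapply(seq_along(gene_trees), function(i) {
      tr <- gene_trees[[i]]
      if (!pick[i]) return(tr)
      m <- spr_move(tr, clade, attach_to)
      if (is.null(m)) {
        skipped <<- skipped + 1L
        return(tr)
      }
      moved <<- c(moved, i)
      m
    })
  })
  if (skipped > 0L) {
    warning(skipped, " gene tree(s) skipped: target clade not monophyletic")
  }
  attr(out, "moved") <- moved
  out
}

# Prune `clade` and re-attach it as sister to the mrca clade of
# `attach_to`. NULL when the clade is not monophyletic or the move is
# impossible.
spr_move <- function(tree, clade, attach_to) {
  if (!all(clade %in% tree$tip.label)) return(NULL)
  if (!all(attach_to %in% tree$tip.label)) return(NULL)
  sets <- node_tip_sets(tree)
  ntip <- length(tree$tip.label)
  cl <- sort(clade)
  hit <- NULL
  for (v in seq_along(sets)) {
    if (length(sets[[v]]) == length(cl) && identical(sort(sets[[v]]), cl)) {
      hit <- v
      break
    }
  }
  if (is.null(hit)) return(NULL)
  sub <- if (hit <= ntip) {
    tr1 <- list(edge = matrix(c(2L, 1L), 1L, 2L),
                tip.label = tree$tip.label[hit], Nnode = 1L,
                edge.length = tree$edge.length[
                  match(hit, tree$edge[, 2L])])
    class(tr1) <- "phylo"
    tr1
  } else {
    ape::extract.clade(tree, hit)
  }
  backbone <- prune_to_taxa(tree, setdiff(tree$tip.label, clade))
  target <- intersect(attach_to, backbone$tip.label)
  if (!length(target)) return(NULL)
  where <- if (length(target) == 1L) {
    match(target, backbone$tip.label)
  } else {
    ape::getMRCA(backbone, target)
  }
  if (where == length(backbone$tip.label) + 1L) return(NULL)  # root
  elen <- backbone$edge.length[match(where, backbone$edge[, 2L])]
  sub$root.edge <- 0
  ape::bind.tree(backbone, sub, where = where, position = elen / 2)
}

#' Simulate a trait under lambda-transformed Brownian motion
#'
#' Draws one multivariate-normal trait vector with covariance
#' `sigma2 *` [phylo_vcv()] around `root_state`.
#'
#' @param tree A `"phylo"` with branch lengths.
#' @param sigma2 Brownian rate (> 0).
#' @param lambda Pagel's lambda in \[0, 1\] (default 1).
#' @param root_state Trait value at the root (default 0).
#' @param seed Integer RNG seed.
#' @return Named numeric vector of tip values.
#' @export
simulate_bm_traits <- function(tree, sigma2 = 1, lambda = 1, root_state = 0,
                               seed = 1) {
  stopifnot(sigma2 > 0)
  C <- phylo_vcv(tree, lambda)
  Lt <- chol(C)
  n <- nrow(C)
  z <- with_seed(seed, stats::rnorm(n))
  out <- root_state + sqrt(sigma2) * drop(crossprod(Lt, z))
  names(out) <- tree$tip.label
  out
}

#' Simulate a flow-cytometry peak series
#'
#' Generates an [fcm_run()] under the partial-endoreplication model:
#' PI peaks at \eqn{F_0 (1 + (2^r - 1) P)} for rounds r = 0, 1, ...,
#' DAPI peaks scaled by the dye factor implied by the requested GC
#' content under the binding-length model of [gc_content()], and
#' multiplicative log-normal noise of coefficient of variation `cv` on
#' every sample peak. At `cv = 0` the derivation functions invert the
#' simulation exactly.
#'
#' @param gs_2c_mbp True 2C genome size (Mbp).
#' @param p True replicated fraction in (0, 1].
#' @param gc_pct True GC content (percent).
#' @param standard List with `gs_2c_mbp`, `gc_pct`, `peak_pi`, and
#'   `df` (the standard's dye factor DAPI/PI).
#' @param n_peaks Number of sample peaks (2C plus endocycles).
#' @param cv Coefficient of variation of the multiplicative noise.
#' @param seed Integer RNG seed.
#' @param binding_length DAPI binding length (must match the value used
#'   at derivation; default 4).
#' @return An [fcm_run()].
#' @export
simulate_fcm_run <- function(gs_2c_mbp, p, gc_pct,
                             standard = list(gs_2c_mbp = 9090,
                                             gc_pct = 38.5,
                                             peak_pi = 400, df = 1),
                             n_peaks = 4, cv = 0, seed = 1,
                             binding_length = 4) {
  stopifnot(p > 0, p <= 1, cv >= 0, n_peaks >= 1)
  f0 <- gs_2c_mbp / standard$gs_2c_mbp * standard$peak_pi
  r <- seq_len(n_peaks) - 1
  mu_pi <- f0 * (1 + (2^r - 1) * p)
  at_s <- 100 - gc_pct
  at_std <- 100 - standard$gc_pct
  df_s <- standard$df * (at_s / at_std)^binding_length
  mu_dapi <- mu_pi * df_s
  noisy <- function(mu, z) {
    if (cv == 0) return(mu)
    sdlog <- sqrt(log(1 + cv^2))
    mu * exp(z * sdlog - sdlog^2 / 2)
  }
  z <- with_seed(seed, stats::rnorm(2 * n_peaks))
  pi_peaks <- noisy(mu_pi, z[seq_len(n_peaks)])
  dapi_peaks <- noisy(mu_dapi, z[n_peaks + seq_len(n_peaks)])
  fcm_run(sample_pi = sort(pi_peaks),
          sample_dapi = sort(dapi_peaks),
          standard_pi = standard$peak_pi,
          standard_dapi = standard$peak_pi * standard$df,
          standard_2c_mbp = standard$gs_2c_mbp,
          standard_gc = standard$gc_pct)
}

# Smooth random field on an nr x nc grid from seeded low-frequency
# Fourier components; standardized to mean 0, sd 1.
smooth_field <- function(nr, nc, n_waves = 24L) {
  xs <- matrix(rep(seq_len(nc), each = nr) / nc, nr, nc)
  ys <- matrix(rep(seq_len(nr), times = nc) / nr, nr, nc)
  f <- matrix(0, nr, nc)
  for (i in seq_len(n_waves)) {
    fr <- stats::runif(2, 0.5, 4)
    ph <- stats::runif(1, 0, 2 * pi)
    amp <- stats::rnorm(1)
    f <- f + amp * sin(2 * pi * (fr[1] * xs + fr[2] * ys) + ph)
  }
  (f - mean(f)) / stats::sd(f)
}

#' Simulate a landscape: DEM, region mosaic, environment, ecoregions
#'
#' A synthetic stand-in for a digital elevation model, coarse botanical
#' recording regions, bioclim-style environmental layers, and an
#' ecoregion map, on a common lon/lat grid. The DEM is a smooth seeded
#' random field rescaled to `elev_range`; regions and ecoregions are
#' nearest-centre mosaics of seeded random centres; environmental
#' layers are smooth fields with a tunable correlation to the DEM.
#'
#' @param extent `c(xmin, xmax, ymin, ymax)` in degrees.
#' @param cell Fine cell size in arc degrees.
#' @param n_regions Number of regions in the mosaic.
#' @param n_env Number of environmental layers.
#' @param dem_cor Correlation between each environmental layer and the
#'   DEM (default 0).
#' @param n_ecoregions Number of ecoregions (default 6).
#' @param elev_range Elevation range in meters (default 0-4000).
#' @param seed Integer RNG seed.
#' @return A list of class `"landscape"` with [grid_raster()]s `dem`,
#'   `regions`, `ecoregions`, and list `env`.
#' @export
simulate_landscape <- function(extent, cell, n_regions = 8L, n_env = 3L,
                               dem_cor = 0, n_ecoregions = 6L,
                               elev_range = c(0, 4000), seed = 1) {
  stopifnot(length(extent) == 4L, extent[2L] > extent[1L],
            extent[4L] > extent[3L], cell > 0)
  nc <- as.integer(round((extent[2L] - extent[1L]) / cell))
  nr <- as.integer(round((extent[4L] - extent[3L]) / cell))
  with_seed(seed, {
    dem_z <- smooth_field(nr, nc)
    dem <- elev_range[1L] +
      (dem_z - min(dem_z)) / diff(range(dem_z)) * diff(elev_range)
    mosaic <- function(k) {
      cx <- stats::runif(k, 1, nc)
      cy <- stats::runif(k, 1, nr)
      xs <- rep(seq_len(nc), each = nr)
      ys <- rep(seq_len(nr), times = nc)
      d2 <- outer(xs, cx, `-`)^2 + outer(ys, cy, `-`)^2
      matrix(max.col(-d2), nr, nc)
    }
    regions <- mosaic(n_regions)
    ecoregions <- mosaic(n_ecoregions)
    dem_std <- (dem_z - mean(dem_z)) / stats::sd(dem_z)
    env <- lapply(seq_len(n_env), function(i) {
      f <- smooth_field(nr, nc)
      v <- dem_cor * dem_std + sqrt(1 - dem_cor^2) * f
      grid_raster(v, extent[1L], extent[4L], cell)
    })
    names(env) <- paste0("env", seq_len(n_env))
    structure(list(
      dem = grid_raster(dem, extent[1L], extent[4L], cell),
      regions = grid_raster(regions, extent[1L], extent[4L], cell),
      ecoregions = grid_raster(ecoregions, extent[1L], extent[4L], cell),
      env = env), class = "landscape")
  })
}

#' Write a complete miniature study to disk
#'
#' Generates and writes every input the analysis modules consume: a
#' species tree with named clades, coalescent gene trees carrying one
#' injected hybrid signal, a per-taxon trait table derived from
#' simulated flow-cytometry runs, the peak table itself, a landscape
#' (DEM, regions, ecoregions, one environmental layer as ASCII grids),
#' and a taxon range table. All content is a pure function of `seed`.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer RNG seed.
#' @param n_genes Number of gene trees (default 200).
#' @return Invisibly, a list with the generated objects and the file
#'   paths (`$files`).
#' @export
make_fixture_suite <- function(dir, seed = 1, n_genes = 200) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cm <- clade_map(
    clades = list(cladeA = c("A1", "A2"), cladeB = c("B1", "B2"),
                  cladeC = c("C1", "C2"), cladeD = c("D1", "D2"),
                  cladeE = c("E1", "E2")),
    fixed = "OUT")
  sp_txt <- paste0("(((((A1:1,A2:1):4,(B1:1,B2:1):4):4,",
                   "((C1:1,C2:1):4,(D1:1,D2:1):4):4):4,",
                   "(E1:1,E2:1):8):4,OUT:16);")
  species <- parse_newick(sp_txt)
  genes <- simulate_gene_trees_msc(species, n_genes, seed = seed)
  genes <- inject_hybrid_signal(genes, clade = c("E1", "E2"),
                                attach_to = c("A1", "A2"), gamma = 0.3,
                                seed = seed + 1L)
  taxa <- species$tip.label
  gs_true <- stats::setNames(
    round(exp(simulate_bm_traits(species, sigma2 = 0.05,
                                 root_state = log(1500),
                                 seed = seed + 2L))), taxa)
  p_true <- stats::setNames(rep(1, length(taxa)), taxa)
  p_true[c("E1", "E2", "A1")] <- c(0.45, 0.55, 0.8)
  gc_true <- stats::setNames(rep(40, length(taxa)), taxa)
  gc_true[c("E1", "E2")] <- c(30, 34)

  runs <- lapply(seq_along(taxa), function(i) {
    r <- simulate_fcm_run(2 * gs_true[i], p_true[i], gc_true[i],
                          cv = 0.01, seed = seed + 10L + i)
    r$id <- taxa[i]
    r
  })
  traits <- do.call(rbind, lapply(runs, derive_traits))
  peaks <- do.call(rbind, lapply(runs, function(r) {
    data.frame(id = r$id,
               pi_peaks = paste(signif(r$sample_pi, 8), collapse = ","),
               dapi_peaks = paste(signif(r$sample_dapi, 8), collapse = ","),
               standard_pi = r$standard_pi, standard_dapi = r$standard_dapi,
               standard_2c_mbp = r$standard_2c_mbp,
               standard_gc = r$standard_gc, stringsAsFactors = FALSE)
  }))

  land <- simulate_landscape(extent = c(-80, -70, -15, -5), cell = 0.05,
                             n_regions = 6L, n_env = 1L, dem_cor = 0.5,
                             seed = seed + 3L)
  ranges <- with_seed(seed + 4L, {
    out <- data.frame(
      taxon = taxa,
      region_ids = vapply(seq_along(taxa), function(i) {
        paste(sort(sample.int(6L, sample.int(3L, 1L))), collapse = ",")
      }, ""),
      elev_min = round(stats::runif(length(taxa), 0, 1500)),
      elev_max = NA_real_, stringsAsFactors = FALSE)
    out$elev_max <- out$elev_min +
      round(stats::runif(length(taxa), 500, 2500))
    out
  })

  files <- list(
    species = file.path(dir, "species.nwk"),
    genes = file.path(dir, "genes.nwk"),
    traits = file.path(dir, "traits.tsv"),
    peaks = file.path(dir, "fcm_peaks.tsv"),
    ranges = file.path(dir, "ranges.tsv"),
    dem = file.path(dir, "dem.asc"),
    regions = file.path(dir, "regions.asc"),
    ecoregions = file.path(dir, "ecoregions.asc"),
    env = file.path(dir, "env1.asc"))
  write_newick(species, files$species)
  write_newick(structure(genes, class = "multiPhylo"), files$genes)
  utils::write.table(traits, files$traits, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(peaks, files$peaks, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(ranges, files$ranges, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  write_ascii_grid(land$dem, files$dem)
  write_ascii_grid(land$regions, files$regions)
  write_ascii_grid(land$ecoregions, files$ecoregions)
  write_ascii_grid(land$env[[1L]], files$env)
  invisible(list(clade_map = cm, species = species, genes = genes,
                 traits = traits, landscape = land, ranges = ranges,
                 gs_true = gs_true, p_true = p_true, gc_true = gc_true,
                 files = files))
}
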