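#' Construct a simple lon/lat grid raster
#'
#' A minimal in-memory raster: a numeric matrix whose rows run north to
#' south and columns west to east, with square cells of `cell` arc
#' degrees anchored at the north-west corner (`xmin`, `ymax`). `NA`
#' marks nodata.
#'
#' @param values Numeric matrix (row 1 = northernmost row).
#' @param xmin Western edge (degrees longitude).
#' @param ymax Northern edge (degrees latitude).
#' @param cell Cell size in arc degrees.
#' @return An object of class `"grid_raster"`.
#' @export
grid_raster <- function(values, xmin, ymax, cell) {
  stopifnot(is.matrix(values), cell > 0)
  structure(list(values = values, xmin = xmin, ymax = ymax, cell = cell),
            class = "grid_raster")
}

#' @export
print.grid_raster <- function(x, ...) {
  cat(sprintf("grid_raster: %d x %d cells of %g deg, NW corner (%g, %g)\n",
              nrow(x$values), ncol(x$values), x$cell, x$xmin, x$ymax))
  invisible(x)
}

# Latitudes of cell centres (north to south).
raster_lats <- function(r) {
  r$ymax - (seq_len(nrow(r$values)) - 0.5) * r$cell
}

# Per-cell area in km^2 using the cos(latitude) spherical approximation.
cell_areas_km2 <- function(r) {
  km_per_deg <- 111.194927  # 2*pi*6371.0088/360
  a <- (r$cell * km_per_deg)^2 * cos(raster_lats(r) * pi / 180)
  matrix(a, nrow(r$values), ncol(r$values))
}

check_coregistered <- function(a, b) {
  if (!identical(dim(a$values), dim(b$values)) ||
      !isTRUE(all.equal(c(a$xmin, a$ymax, a$cell),
                        c(b$xmin, b$ymax, b$cell)))) {
    stop("rasters are not co-registered (extent, cell size, or ",
         "dimensions differ)")
  }
  invisible(TRUE)
}

#' Read/write headered ASCII grids
#'
#' Plain-text rasters in the conventional six-line headered format
#' (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`,
#' `NODATA_value`, then rows north to south).
#'
#' @param file Path.
#' @return For `read_ascii_grid`, a [grid_raster()].
#' @export
read_ascii_grid <- function(file) {
  hdr <- readLines(file, n = 6L)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  h <- stats::setNames(as.numeric(kv[, 2L]), tolower(kv[, 1L]))
  vals <- as.matrix(utils::read.table(file, skip = 6L))
  dimnames(vals) <- NULL
  vals[vals == h[["nodata_value"]]] <- NA
  grid_raster(vals, xmin = h[["xllcorner"]],
              ymax = h[["yllcorner"]] + h[["nrows"]] * h[["cellsize"]],
              cell = h[["cellsize"]])
}

#' @param r A [grid_raster()].
#' @param nodata Value written for `NA` cells.
#' @rdname read_ascii_grid
#' @export
write_ascii_grid <- function(r, file, nodata = -9999) {
  stopifnot(inherits(r, "grid_raster"))
  v <- r$values
  v[is.na(v)] <- nodata
  hdr <- c(
    paste("ncols", ncol(v)), paste("nrows", nrow(v)),
    paste("xllcorner", format(r$xmin, digits = 12)),
    paste("yllcorner", format(r$ymax - nrow(v) * r$cell, digits = 12)),
    paste("cellsize", format(r$cell, digits = 12)),
    paste("NODATA_value", nodata))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(v, con, row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Define a taxon range from regions and an elevation band
#'
#' @param taxon Taxon identifier.
#' @param region_ids Vector of region identifiers (e.g. level-3
#'   botanical recording areas) where the taxon is recorded.
#' @param elev_min,elev_max Elevation band in meters (inclusive).
#' @return A list of class `"taxon_range"`.
#' @export
taxon_range <- function(taxon, region_ids, elev_min, elev_max) {
  stopifnot(length(region_ids) >= 1L, elev_min <= elev_max)
  structure(list(taxon = taxon, region_ids = region_ids,
                 elev_min = elev_min, elev_max = elev_max),
            class = "taxon_range")
}

#' Reconstruct a pseudo-occurrence range mask
#'
#' A fine-grid cell is in range iff its region id belongs to the
#' taxon's recorded regions and its elevation lies inside the taxon's
#' band (both bounds inclusive, since reported minima and maxima are
#' attained values). Cells with missing region or elevation are out of
#' range.
#'
#' @param tr A [taxon_range()].
#' @param region_mask [grid_raster()] of region ids.
#' @param dem [grid_raster()] of elevations (m), co-registered with
#'   `region_mask`.
#' @return A [grid_raster()] with logical values.
#' @export
reconstruct_range <- function(tr, region_mask, dem) {
  stopifnot(inherits(tr, "taxon_range"))
  check_coregistered(region_mask, dem)
  inreg <- matrix(region_mask$values %in% tr$region_ids,
                  nrow(region_mask$values))
  inelev <- !is.na(dem$values) & dem$values >= tr$elev_min &
    dem$values <= tr$elev_max
  grid_raster(inreg & inelev, region_mask$xmin, region_mask$ymax,
              region_mask$cell)
}

#' Coarse-grid occupancy of one taxon
#'
#' Aggregates a fine-resolution range mask onto a coarse grid (e.g.
#' 0.5 arc degree cells), recording per coarse cell the occupied area
#' (km^2, fine-cell areas weighted by cos latitude) and a presence flag
#' that is set when the occupied area strictly exceeds `presence_frac`
#' of the coarse cell's area.
#'
#' @param mask Logical [grid_raster()] from [reconstruct_range()].
#' @param coarse_cell Coarse cell size in arc degrees; must be an
#'   integer multiple of the fine cell size.
#' @param presence_frac Presence threshold as a fraction of cell area
#'   (default 0.05).
#' @return A list of class `"occupancy"` with `area` and `presence`
#'   [grid_raster()]s on the coarse grid, plus `cell_area` (total coarse
#'   cell areas).
#' @export
grid_occupancy <- function(mask, coarse_cell, presence_frac = 0.05) {
  stopifnot(inherits(mask, "grid_raster"))
  f <- coarse_cell / mask$cell
  if (abs(f - round(f)) > 1e-8) {
    stop("coarse cell size must be an integer multiple of the fine ",
         "cell size")
  }
  f <- as.integer(round(f))
  v <- mask$values
  nr <- nrow(v); nc <- ncol(v)
  if (nr %% f != 0L || nc %% f != 0L) {
    stop("raster dimensions are not divisible by the aggregation factor")
  }
  area <- cell_areas_km2(mask)
  occ_fine <- area * (!is.na(v) & v != 0)
  cr <- nr %/% f; cc <- nc %/% f
  block_sum <- function(m) {
    idx_r <- rep(seq_len(cr), each = f)
    idx_c <- rep(seq_len(cc), each = f)
    t(rowsum(t(rowsum(m, idx_r)), idx_c))
  }
  occ <- block_sum(occ_fine)
  tot <- block_sum(area)
  pres <- occ > presence_frac * tot
  structure(list(
    area = grid_raster(occ, mask$xmin, mask$ymax, coarse_cell),
    presence = grid_raster(pres, mask$xmin, mask$ymax, coarse_cell),
    cell_area = grid_raster(tot, mask$xmin, mask$ymax, coarse_cell)),
    class = "occupancy")
}

#' Build the multi-taxon occupancy table
#'
#' @param ranges A list of [taxon_range()] objects.
#' @param region_mask,dem Co-registered fine [grid_raster()]s.
#' @param coarse_cell Coarse cell size in arc degrees (default 0.5).
#' @param presence_frac Presence threshold fraction (default 0.05).
#' @return A list of class `"occupancy_set"`: per-taxon `area` and
#'   `presence` matrices (named lists), `cell_area`, and the coarse
#'   georeference.
#' @export
occupancy_set <- function(ranges, region_mask, dem, coarse_cell = 0.5,
                          presence_frac = 0.05) {
  occs <- lapply(ranges, function(tr) {
    grid_occupancy(reconstruct_range(tr, region_mask, dem), coarse_cell,
                   presence_frac)
  })
  taxa <- vapply(ranges, function(tr) tr$taxon, "")
  names(occs) <- taxa
  structure(list(
    taxa = taxa,
    area = lapply(occs, function(o) o$area$values),
    presence = lapply(occs, function(o) o$presence$values),
    cell_area = occs[[1L]]$cell_area,
    xmin = occs[[1L]]$area$xmin, ymax = occs[[1L]]$area$ymax,
    cell = occs[[1L]]$area$cell), class = "occupancy_set")
}

#' Area-weighted trait surface
#'
#' Per coarse cell, the mean of the trait over the taxa present there,
#' weighted by each taxon's occupied area in the cell; nodata where no
#' taxon is present.
#'
#' @param occ An [occupancy_set()].
#' @param traits Named numeric vector of per-taxon trait values; a
#'   value is required for every taxon with any presence.
#' @return A [grid_raster()] on the coarse grid.
#' @export
weighted_trait_surface <- function(occ, traits) {
  stopifnot(inherits(occ, "occupancy_set"))
  present_taxa <- occ$taxa[vapply(occ$presence, any, NA)]
  missing <- present_taxa[!present_taxa %in% names(traits) |
                            is.na(traits[present_taxa])]
  if (length(missing)) {
    stop("missing trait value for taxa: ",
         paste(sQuote(missing), collapse = ", "))
  }
  num <- 0 * occ$cell_area$values
  den <- num
  for (tx in occ$taxa) {
    w <- occ$area[[tx]] * occ$presence[[tx]]
    if (!tx %in% names(traits)) next
    num <- num + w * traits[[tx]]
    den <- den + w
  }
  out <- num / den
  out[den == 0] <- NA
  grid_raster(out, occ$xmin, occ$ymax, occ$cell)
}

#' Species density surfaces by endoreplication type
#'
#' @param occ An [occupancy_set()].
#' @param endo_type Named character vector (`"PE"`/`"CE"`) per taxon.
#' @return A list of [grid_raster()]s: `total`, `pe`, `ce`, and
#'   `ratio` (PE/CE; nodata where the CE count is zero), plus every
#'   count nodata where no taxon is present.
#' @export
species_density <- function(occ, endo_type) {
  stopifnot(inherits(occ, "occupancy_set"))
  zero <- 0 * occ$cell_area$values
  tot <- zero; pe <- zero; ce <- zero
  for (tx in occ$taxa) {
    p <- occ$presence[[tx]]
    tot <- tot + p
    if (identical(endo_type[[tx]], "PE")) pe <- pe + p
    if (identical(endo_type[[tx]], "CE")) ce <- ce + p
  }
  ratio <- pe / ce
  ratio[ce == 0] <- NA
  empty <- tot == 0
  tot[empty] <- NA; pe[empty] <- NA; ce[empty] <- NA; ratio[empty] <- NA
  g <- function(v) grid_raster(v, occ$xmin, occ$ymax, occ$cell)
  list(total = g(tot), pe = g(pe), ce = g(ce), ratio = g(ratio))
}

#' Per-ecoregion value distributions of a surface
#'
#' @param surface A [grid_raster()] (e.g. from
#'   [weighted_trait_surface()]).
#' @param ecoregions Co-registered [grid_raster()] of ecoregion ids.
#' @return A named list: per ecoregion, the vector of non-nodata
#'   surface values in its cells (possibly empty).
#' @export
ecoregion_summary <- function(surface, ecoregions) {
  check_coregistered(surface, ecoregions)
  ids <- sort(unique(stats::na.omit(as.vector(ecoregions$values))))
  out <- lapply(ids, function(i) {
    v <- surface$values[!is.na(ecoregions$values) & ecoregions$values == i]
    v[!is.na(v)]
  })
  names(out) <- as.character(ids)
  out
}

#' Environmental statistics over a taxon's range
#'
#' Percentiles (10, 25, 50, 75, 90), mean, and standard deviation of an
#' environmental layer over a taxon's in-range cells, plus the
#' percentile bounds used by the uncertainty analyses: the 47.5-52.5
#' and 45-55 percent pairs bracketing the median.
#'
#' @param mask Logical [grid_raster()] of the taxon's range.
#' @param env Co-registered [grid_raster()] of the environmental layer.
#' @return A list with `percentiles` (named vector), `mean`, `sd`, `n`,
#'   `median_pm2.5` (47.5/52.5 bounds) and `median_pm5` (45/55 bounds).
#' @export
taxon_env_stats <- function(mask, env) {
  check_coregistered(mask, env)
  vals <- env$values[!is.na(mask$values) & mask$values != 0]
  vals <- vals[!is.na(vals)]
  if (!length(vals)) stop("taxon range contains no cells with data")
  q <- stats::quantile(vals, c(.10, .25, .50, .75, .90), names = TRUE)
  list(percentiles = q,
       mean = mean(vals), sd = stats::sd(vals), n = length(vals),
       median_pm2.5 = unname(stats::quantile(vals, c(.475, .525))),
       median_pm5 = unname(stats::quantile(vals, c(.45, .55))))
}
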