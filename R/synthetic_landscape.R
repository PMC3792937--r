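#' Spatially autocorrelated random field
#'
#' White noise smoothed by a separable Gaussian kernel (reflecting edges) and
#' standardized to mean 0, sd 1. Used for synthetic environmental predictors:
#' distribution-model learners need spatial structure to beat chance.
#'
#' @param n_rows,n_cols Field dimensions.
#' @param sigma Gaussian smoothing radius in cells.
#' @return A numeric matrix.
#' @export
smooth_field <- function(n_rows, n_cols, sigma = 6) {
  z <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  half <- max(1L, ceiling(3 * sigma))
  g <- stats::dnorm(seq(-half, half), sd = sigma)
  g <- g / sum(g)
  conv1 <- function(v) {
    n <- length(v)
    idx <- c(rev(seq_len(half)), seq_len(n), n + 1 - seq_len(half))  # reflect
    vp <- v[pmin(pmax(idx, 1L), n)]
    stats::filter(vp, g, sides = 2)[half + seq_len(n)]
  }
  z <- apply(z, 2L, conv1)
  z <- t(apply(z, 1L, conv1))
  (z - mean(z)) / stats::sd(z)
}

#' Generate a two-resolution synthetic world
#'
#' Builds a fine grid of spatially autocorrelated continuous predictors plus
#' one categorical land-cover layer, a set of species whose true habitat
#' suitability is a logistic function of a random linear combination of
#' predictors, presence-only records sampled inside the true ranges, and
#' axis-aligned rectangular reserves of known total area. Everything is
#' deterministic for a fixed seed.
#'
#' @param seed Integer seed; the world is bit-identical across calls.
#' @param fine_spec Fine-resolution `grid_spec`; dimensions must be divisible
#'   by `k`.
#' @param k Nesting factor: one coarse cell covers `k x k` fine cells.
#' @param n_species Number of species (>= 1).
#' @param n_predictors Number of continuous predictor layers.
#' @param records_per_species Integer vector (recycled to `n_species`) of
#'   record counts; entries must be >= 1 and no larger than the species'
#'   true-range cell count. A value of 1 emulates the single-record species
#'   case.
#' @param reserve_fraction Fraction of the total extent area covered by
#'   reserves, in `[0, 0.5]`; realized total area matches within one fine
#'   cell's area.
#' @param range_quantiles Optional per-species suitability quantiles defining
#'   the true range (`suitability >= quantile`); default drawn in
#'   `[0.70, 0.90]`.
#' @param coef_sd Spread of the species' predictor coefficients; larger values
#'   give stronger, easier-to-recover environmental signal.
#' @return An object of class `synthetic_world`.
#' @export
make_world <- function(seed, fine_spec, k = 4L, n_species = 6L, n_predictors = 4L,
                       records_per_species = 30L, reserve_fraction = 0.1,
                       range_quantiles = NULL, coef_sd = 3) {
  if (n_species < 1L) stop("n_species must be >= 1")
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  if (reserve_fraction < 0 || reserve_fraction > 0.5)
    stop("reserve_fraction must be in [0, 0.5]")
  records_per_species <- rep_len(as.integer(records_per_species), n_species)
  if (any(records_per_species < 1L)) stop("records_per_species entries must be >= 1")
  coarse_spec <- coarsen_spec(fine_spec, k)

  with_seed(seed, {
    nr <- fine_spec$n_rows; nc <- fine_spec$n_cols
    # continuous predictors
    preds <- lapply(seq_len(n_predictors), function(i) smooth_field(nr, nc, sigma = 4 + 2 * (i %% 3)))
    names(preds) <- sprintf("env%02d", seq_len(n_predictors))
    # one categorical land-cover layer: quartiles of an extra smooth field
    lc_field <- smooth_field(nr, nc, sigma = 5)
    qs <- stats::quantile(lc_field, c(0.25, 0.5, 0.75))
    landcover <- matrix(findInterval(lc_field, qs) + 1L, nr, nc)
    attr(landcover, "levels") <- as.character(1:4)

    if (is.null(range_quantiles)) range_quantiles <- stats::runif(n_species, 0.70, 0.90)
    range_quantiles <- rep_len(range_quantiles, n_species)

    spp <- sprintf("species_%02d", seq_len(n_species))
    suit <- vector("list", n_species); names(suit) <- spp
    ranges <- vector("list", n_species); names(ranges) <- spp
    rec_list <- vector("list", n_species)
    for (i in seq_len(n_species)) {
      beta <- stats::rnorm(n_predictors, sd = coef_sd)
      lin <- Reduce(`+`, Map(function(p, b) p * b, preds, as.list(beta)))
      lin <- lin + 0.5 * coef_sd * (landcover == ((i %% 4) + 1L))  # mild land-cover affinity
      s <- stats::plogis(lin - stats::quantile(lin, 0.5))
      suit[[i]] <- s
      thr <- stats::quantile(s, range_quantiles[i])
      rng <- (s >= thr) * 1L
      ranges[[i]] <- rng
      cells <- layer_which(rng, rng == 1L)
      if (records_per_species[i] > length(cells))
        stop(sprintf("species %s: requested %d records but true range has only %d cells",
                     spp[i], records_per_species[i], length(cells)))
      chosen <- if (length(cells) == 1L) cells else
        sample(cells, records_per_species[i])
      ctr <- cell_centres(fine_spec, chosen)
      jit <- fine_spec$cell_size * (stats::runif(2 * length(chosen), -0.499, 0.499))
      rec_list[[i]] <- data.frame(
        species = spp[i],
        lon = ctr[, "lon"] + jit[seq_along(chosen)],
        lat = ctr[, "lat"] + jit[length(chosen) + seq_along(chosen)],
        stringsAsFactors = FALSE)
    }
    records <- do.call(rbind, rec_list)

    reserves <- make_reserves(fine_spec, reserve_fraction)

    structure(
      list(fine_spec = fine_spec, coarse_spec = coarse_spec, k = k,
           predictors = predictor_stack(fine_spec, c(preds, list(landcover = landcover)),
                                        categorical = "landcover"),
           true_suitability = suit, true_range = ranges,
           records = records, reserves = reserves$polygons,
           reserve_area = reserves$total_area,
           params = list(seed = seed, n_species = n_species,
                         n_predictors = n_predictors,
                         records_per_species = records_per_species,
                         reserve_fraction = reserve_fraction,
                         range_quantiles = range_quantiles, coef_sd = coef_sd)),
      class = "synthetic_world")
  })
}

# disjoint cell-aligned rectangles summing to fraction * extent area within
# one fine cell's area; exact accounting is why reserves are rectangles
make_reserves <- function(spec, fraction) {
  s <- spec$cell_size
  cell_area <- s^2
  total <- n_cells(spec) * cell_area
  target <- fraction * total
  if (target < cell_area / 2) return(list(polygons = list(), total_area = 0))
  occ <- matrix(FALSE, spec$n_rows, spec$n_cols)
  polys <- list()
  area <- 0
  tries <- 0L
  while (target - area > cell_area && tries < 5000L) {
    tries <- tries + 1L
    w <- sample(2:8, 1L); h <- sample(2:8, 1L)
    need <- (target - area) / cell_area
    if (w * h > need) { w <- max(1L, floor(sqrt(need))); h <- max(1L, floor(need / max(w, 1L))) }
    if (w < 1L || h < 1L) break
    r0 <- sample(seq_len(spec$n_rows - h + 1L), 1L)
    c0 <- sample(seq_len(spec$n_cols - w + 1L), 1L)
    block <- occ[r0:(r0 + h - 1L), c0:(c0 + w - 1L)]
    if (any(block)) next
    occ[r0:(r0 + h - 1L), c0:(c0 + w - 1L)] <- TRUE
    lon0 <- spec$origin_lon + (c0 - 1L) * s
    lat1 <- spec$origin_lat - (r0 - 1L) * s
    polys[[length(polys) + 1L]] <- rect_reserve(lon0, lat1 - h * s, lon0 + w * s, lat1)
    area <- area + w * h * cell_area
  }
  list(polygons = polys, total_area = area)
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("synthetic_world: %d species on %dx%d fine / %dx%d coarse grid (k=%d)\n",
              x$params$n_species, x$fine_spec$n_rows, x$fine_spec$n_cols,
              x$coarse_spec$n_rows, x$coarse_spec$n_cols, x$k))
  cat(sprintf("  %d records, %d reserves (area %.4g deg^2)\n",
              nrow(x$records), length(x$reserves), x$reserve_area))
  invisible(x)
}

#' Ground-truth metrics of a synthetic world
#'
#' Computed from the true binary ranges and the reserve polygons only; no
#' model output is involved, so these serve as the oracle for recovery tests.
#'
#' @param world A `synthetic_world`.
#' @return Data frame with `species`, `true_range_cells`,
#'   `true_protected_fraction` (area of range intersected by reserves over
#'   range area).
#' @export
true_metrics <- function(world) {
  cov <- reserve_coverage(world$fine_spec, world$reserves)
  out <- lapply(names(world$true_range), function(sp) {
    rng <- world$true_range[[sp]]
    n <- sum(rng)
    frac <- if (n == 0) 0 else sum(cov[rng == 1L]) / n
    data.frame(species = sp, true_range_cells = n, true_protected_fraction = frac,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write a synthetic world to disk in standard formats
#'
#' Predictors as ESRI ASCII grids, records as CSV, reserves as GeoJSON.
#'
#' @param world A `synthetic_world`.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  st <- world$predictors
  for (nm in names(st$layers))
    write_ascii_grid(st$layers[[nm]], st$grid, file.path(dir, paste0(nm, ".asc")))
  write_records_csv(world$records, file.path(dir, "records.csv"))
  write_reserves_geojson(world$reserves, file.path(dir, "reserves.geojson"))
  invisible(dir)
}
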