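#' Permutation-null Pearson correlation test
#'
#' The observed Pearson r is contrasted with the distribution of r under
#' random permutations of `y` (with `x` fixed); the p-value is the one-sided
#' upper-tail probability `(1 + #{r_perm >= r_obs}) / (1 + n_perm)`.
#' Non-random correlation is conventionally declared at `p <= 0.05`.
#'
#' @param x,y Numeric vectors of equal length >= 3, finite, non-constant.
#' @param n_perm Number of Monte-Carlo permutations (default 30000).
#' @param seed Integer seed.
#' @return List: `r_obs`, `p`, `n_perm`.
#' @export
permutation_correlation <- function(x, y, n_perm = 30000L, seed = 1L) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 pairs")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("values must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance in x or y")
  r_obs <- stats::cor(x, y)
  xc <- x - mean(x)
  yc <- y - mean(y)
  denom <- sqrt(sum(xc^2)) * sqrt(sum(yc^2))
  count <- 0L
  with_seed(seed, {
    block <- max(1L, min(n_perm, floor(4e6 / n)))
    done <- 0L
    while (done < n_perm) {
      b <- min(block, n_perm - done)
      P <- vapply(seq_len(b), function(i) yc[sample.int(n)], numeric(n))
      r_perm <- as.vector(crossprod(xc, P)) / denom
      count <- count + sum(r_perm >= r_obs)
      done <- done + b
    }
  })
  list(r_obs = r_obs, p = (1 + count) / (1 + n_perm), n_perm = n_perm)
}

#' Arcsine-square-root transform of a percentage
#'
#' `asin(sqrt(p / 100))` in radians; percentages above 100 (over-achieved
#' targets) are capped to 100 first.
#'
#' @param p Percentages in `[0, 100]` (values > 100 capped).
#' @return Transformed values in `[0, pi/2]`.
#' @export
arcsine_pct <- function(p) {
  p <- pmin(p, 100)
  if (any(p < 0 | p > 100, na.rm = TRUE)) stop("percentages must be in [0, 100]")
  asin(sqrt(p / 100))
}

#' Top-priority envelope of a layer
#'
#' Scans the unique scores as thresholds and picks the one whose
#' strictly-above cell count is closest to `fraction` of the scored cells;
#' count ties resolve to the fewer-cell (larger) threshold. With heavy ties
#' the realized fraction can deviate from the request.
#'
#' @param layer Numeric priority matrix (`NA` = unscored).
#' @param fraction Requested envelope fraction (default 0.01, the "best 1%").
#' @return List: `cells` (ids strictly above the threshold), `threshold`,
#'   `realized_fraction`.
#' @export
priority_envelope <- function(layer, fraction = 0.01) {
  v <- as.numeric(layer)
  scored <- !is.na(v)
  if (!any(scored)) stop("layer has no scored cells")
  u <- sort(unique(v[scored]))
  if (length(u) < 2L) stop("constant layer: no meaningful envelope")
  counts <- vapply(u, function(th) sum(v[scored] > th), numeric(1))
  want <- fraction * sum(scored)
  err <- abs(counts - want)
  best <- max(which(err == min(err)))          # ties -> fewer cells
  th <- u[best]
  cells <- layer_which(layer, !is.na(layer) & layer > th)
  list(cells = cells, threshold = th,
       realized_fraction = length(cells) / sum(scored))
}

#' Nestedness of a fine envelope within a coarse envelope
#'
#' Percentage of fine-scale top-priority cells whose parent coarse cell is
#' itself in the coarse top-priority envelope.
#'
#' @param fine_cells Fine envelope cell ids (non-empty).
#' @param coarse_cells Coarse envelope cell ids.
#' @param parents Integer parent map from [parent_map()] (fine id -> coarse
#'   id).
#' @return Percentage in `[0, 100]`.
#' @export
nestedness <- function(fine_cells, coarse_cells, parents) {
  if (!length(fine_cells)) stop("fine envelope is empty")
  100 * mean(parents[fine_cells] %in% coarse_cells)
}

#' Pair fine- and coarse-resolution cell values across nested grids
#'
#' In `replicate` mode (default) each fine cell's value is paired with its
#' parent coarse cell's value; in `aggregate` mode fine values are averaged
#' per coarse cell and paired with the coarse value.
#'
#' @param coarse_layer,fine_layer Value matrices on the two grids.
#' @param fine_spec,coarse_spec Nested `grid_spec`s.
#' @param mode `"replicate"` or `"aggregate"`.
#' @return Data frame with columns `coarse`, `fine` (pairs with any `NA`
#'   dropped).
#' @export
cross_scale_cell_pairs <- function(coarse_layer, fine_layer, fine_spec, coarse_spec,
                                   mode = c("replicate", "aggregate")) {
  mode <- match.arg(mode)
  check_layer(coarse_layer, coarse_spec)
  check_layer(fine_layer, fine_spec)
  par <- parent_map(fine_spec, coarse_spec)
  fid <- seq_len(n_cells(fine_spec))
  fv <- layer_values(fine_layer, fid)
  cv <- layer_values(coarse_layer, par)
  if (mode == "replicate") {
    out <- data.frame(coarse = cv, fine = fv)
  } else {
    agg <- tapply(fv, par, function(z) mean(z, na.rm = TRUE))
    cid <- as.integer(names(agg))
    out <- data.frame(coarse = layer_values(coarse_layer, cid),
                      fine = as.numeric(agg))
  }
  out[stats::complete.cases(out) & is.finite(out$fine) & is.finite(out$coarse), ]
}
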