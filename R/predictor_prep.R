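#' Predictor stack
#'
#' A named collection of layers sharing one grid: continuous layers plus at
#' most one categorical (land-cover) layer, which is exempt from collinearity
#' screening.
#'
#' @param grid A `grid_spec`.
#' @param layers Named list of matrices.
#' @param categorical Name of the categorical layer, or `NULL`.
#' @return An object of class `predictor_stack`.
#' @export
predictor_stack <- function(grid, layers, categorical = NULL) {
  stopifnot(is.list(layers), !is.null(names(layers)), all(nzchar(names(layers))))
  for (nm in names(layers)) check_layer(layers[[nm]], grid)
  if (!is.null(categorical) && !categorical %in% names(layers))
    stop("categorical layer '", categorical, "' not found in layers")
  structure(list(grid = grid, layers = layers, categorical = categorical,
                 vif = NULL, drop_log = NULL),
            class = "predictor_stack")
}

#' @export
print.predictor_stack <- function(x, ...) {
  cat(sprintf("predictor_stack: %d layers on %dx%d grid%s\n",
              length(x$layers), x$grid$n_rows, x$grid$n_cols,
              if (is.null(x$categorical)) "" else sprintf(" (categorical: %s)", x$categorical)))
  if (!is.null(x$vif)) {
    cat("  VIFs: ", paste(sprintf("%s=%.2f", names(x$vif), x$vif), collapse = ", "), "\n")
  }
  invisible(x)
}

continuous_names <- function(stack) setdiff(names(stack$layers), stack$categorical)

#' Aggregate a fine layer onto a nested coarse grid
#'
#' Continuous layers take the mean of the `k^2` fine children (missing values
#' excluded); categorical layers take the modal class, ties broken by the
#' smallest class label.
#'
#' @param fine_layer Matrix on the fine grid.
#' @param fine_spec,coarse_spec Nested `grid_spec`s.
#' @param categorical Is the layer categorical?
#' @return Matrix on the coarse grid.
#' @export
aggregate_layer <- function(fine_layer, fine_spec, coarse_spec, categorical = FALSE) {
  k <- nesting_factor(coarse_spec, fine_spec)
  check_layer(fine_layer, fine_spec)
  nrc <- coarse_spec$n_rows; ncc <- coarse_spec$n_cols
  out <- matrix(NA_real_, nrc, ncc)
  ridx <- (seq_len(fine_spec$n_rows) - 1L) %/% k + 1L
  cidx <- (seq_len(fine_spec$n_cols) - 1L) %/% k + 1L
  grp <- (rep(cidx, each = fine_spec$n_rows) - 1L) * nrc + rep(ridx, fine_spec$n_cols)
  v <- as.vector(fine_layer)
  if (categorical) {
    for (g in seq_len(nrc * ncc)) {
      vals <- v[grp == g]
      vals <- vals[!is.na(vals)]
      if (!length(vals)) next
      tab <- table(vals)
      win <- names(tab)[tab == max(tab)]
      out[g] <- suppressWarnings(min(as.numeric(win)))  # tie -> smallest label code
      if (is.na(out[g])) out[g] <- sort(win)[1]
    }
    lv <- attr(fine_layer, "levels")
    if (!is.null(lv)) attr(out, "levels") <- lv
  } else {
    sums <- tapply(v, grp, function(x) mean(x, na.rm = TRUE))
    out[as.integer(names(sums))] <- as.numeric(sums)
    out[is.nan(out)] <- NA_real_
  }
  out
}

#' Aggregate a whole predictor stack to the coarse grid
#' @param stack A `predictor_stack` on the fine grid.
#' @param coarse_spec Nested coarse `grid_spec`.
#' @return A `predictor_stack` on the coarse grid.
#' @export
aggregate_stack <- function(stack, coarse_spec) {
  layers <- lapply(names(stack$layers), function(nm)
    aggregate_layer(stack$layers[[nm]], stack$grid, coarse_spec,
                    categorical = identical(nm, stack$categorical)))
  names(layers) <- names(stack$layers)
  predictor_stack(coarse_spec, layers, categorical = stack$categorical)
}

# VIF of each column of X given the others, over complete rows
vif_values <- function(X) {
  p <- ncol(X)
  vapply(seq_len(p), function(j) {
    y <- X[, j]
    if (stats::var(y) < 1e-300) return(Inf)  # constant layer carries no information
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), y)
    rss <- sum(fit$residuals^2)
    tss <- sum((y - mean(y))^2)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
}

#' Screen collinear predictors by variance-inflation factor
#'
#' VIF of layer j is `1 / (1 - R^2_j)` from an ordinary least-squares
#' regression of layer j on all other retained continuous layers over cells
#' with no missing values. The largest-VIF layer is dropped (ties broken by
#' layer-name order), and the procedure repeats until every retained
#' continuous layer has VIF below `threshold`. The categorical layer is exempt
#' and always retained.
#'
#' @param stack A `predictor_stack` with at least 2 continuous layers.
#' @param threshold VIF threshold (default 5).
#' @return The screened `predictor_stack`, with `$vif` (named VIFs of retained
#'   continuous layers) and `$drop_log` (data frame: layer, vif_at_drop,
#'   iteration).
#' @export
vif_screen <- function(stack, threshold = 5) {
  keep <- continuous_names(stack)
  if (length(keep) < 2L) {
    warning("fewer than 2 continuous layers; nothing to screen")
    stack$vif <- stats::setNames(rep(1, length(keep)), keep)
    stack$drop_log <- data.frame(layer = character(), vif_at_drop = numeric(),
                                 iteration = integer())
    return(stack)
  }
  mats <- lapply(stack$layers[keep], as.vector)
  X_all <- do.call(cbind, mats)
  ok <- stats::complete.cases(X_all)        # listwise deletion
  X_all <- X_all[ok, , drop = FALSE]
  drop_log <- data.frame(layer = character(), vif_at_drop = numeric(),
                         iteration = integer(), stringsAsFactors = FALSE)
  it <- 0L
  repeat {
    if (length(keep) < 2L) { v <- stats::setNames(rep(1, length(keep)), keep); break }
    X <- X_all[, keep, drop = FALSE]
    v <- stats::setNames(vif_values(X), keep)
    if (all(v < threshold)) break
    it <- it + 1L
    worst <- max(v)
    cand <- sort(names(v)[v == worst])[1]   # ties -> first by name
    drop_log <- rbind(drop_log,
                      data.frame(layer = cand, vif_at_drop = worst, iteration = it,
                                 stringsAsFactors = FALSE))
    keep <- setdiff(keep, cand)
  }
  out <- stack
  out$layers <- stack$layers[c(keep, stack$categorical)]
  out$vif <- v
  out$drop_log <- drop_log
  out
}
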