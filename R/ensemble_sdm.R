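#' Sample pseudo-absence cells
#'
#' Draws `n` distinct background cells uniformly, without replacement, from
#' the grid cells not holding a presence. Fixed seeds give identical draws.
#'
#' @param spec A `grid_spec`.
#' @param presence_cells Integer ids of presence cells.
#' @param n Number of pseudo-absences (500 at the coarse/continental level and
#'   200 at the fine/regional level by convention).
#' @param seed Integer seed.
#' @return Sorted integer cell ids.
#' @export
sample_pseudo_absences <- function(spec, presence_cells, n, seed) {
  if (n < 1L) stop("n must be >= 1")
  pool <- setdiff(seq_len(n_cells(spec)), presence_cells)
  if (length(pool) < n)
    stop(sprintf("cannot sample %d pseudo-absences: only %d non-presence cells available (deficit %d)",
                 n, length(pool), n - length(pool)))
  with_seed(seed, sort(if (length(pool) == 1L) pool else sample(pool, n)))
}

#' Rank-based AUC (Mann-Whitney form)
#'
#' The probability that a randomly chosen positive outscores a randomly
#' chosen negative, ties counted one half.
#'
#' @param labels 0/1 vector (both classes present).
#' @param scores Numeric scores.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(labels, scores) {
  labels <- as.integer(labels)
  np <- sum(labels == 1L); nn <- sum(labels == 0L)
  if (np == 0L || nn == 0L) stop("AUC requires both classes")
  r <- rank(scores)
  (sum(r[labels == 1L]) - np * (np + 1) / 2) / (np * nn)
}

# stratified fold assignment; every fold gets >= 1 member of each class
make_folds <- function(labels, k, seed) {
  with_seed(seed, {
    fold <- integer(length(labels))
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    fold
  })
}

# design matrix: continuous layers as-is, categorical one-hot (all levels)
build_design <- function(stack, cells) {
  cont <- continuous_names(stack)
  X <- vapply(cont, function(nm) layer_values(stack$layers[[nm]], cells),
              numeric(length(cells)))
  if (length(cells) == 1L) X <- matrix(X, nrow = 1L, dimnames = list(NULL, cont))
  if (!is.null(stack$categorical)) {
    lc <- layer_values(stack$layers[[stack$categorical]], cells)
    lv <- attr(stack$layers[[stack$categorical]], "levels")
    if (is.null(lv)) lv <- as.character(sort(unique(lc)))
    hot <- vapply(lv, function(l) as.numeric(lc == as.numeric(l)), numeric(length(cells)))
    if (length(cells) == 1L) hot <- matrix(hot, nrow = 1L)
    colnames(hot) <- paste0(stack$categorical, "_", lv)
    X <- cbind(X, hot)
  }
  X
}

#' Fit an AUC-weighted ensemble of suitability models
#'
#' Each learner is scored by mean held-out AUC over stratified
#' cross-validation folds, then refitted on all data. The consensus habitat
#' suitability is the AUC-weighted average of the predictions of learners
#' with AUC above `auc_cutoff`; learners at or below the cutoff get weight 0.
#' If no learner passes, the result is flagged unusable.
#'
#' @param stack A screened `predictor_stack`.
#' @param presence_cells,absence_cells Integer cell ids of the two classes.
#' @param learners Named list of [sdm_learner()]s.
#' @param folds Nominal fold count; effectively
#'   `min(folds, n_presences, n_absences)` so each held-out fold contains both
#'   classes.
#' @param seed Integer seed (folds and any learner randomness).
#' @param auc_cutoff Weight cutoff (default 0.7).
#' @return An `ensemble_result`: per-learner `auc` and `weights`, `consensus`
#'   suitability layer in `[0, 1]`, training `scores`/`labels` at the
#'   presence/absence cells, and `usable` flag.
#' @export
fit_ensemble <- function(stack, presence_cells, absence_cells,
                         learners = default_learners(), folds = 10L, seed = 1L,
                         auc_cutoff = 0.7) {
  if (length(presence_cells) < 2L) stop("need at least 2 presences to fit an ensemble")
  if (!length(learners)) stop("learner set must be non-empty")
  cells <- c(presence_cells, absence_cells)
  y <- c(rep(1L, length(presence_cells)), rep(0L, length(absence_cells)))
  X <- build_design(stack, cells)
  ok <- stats::complete.cases(X)
  X <- X[ok, , drop = FALSE]; y <- y[ok]; cells <- cells[ok]
  k <- min(folds, sum(y == 1L), sum(y == 0L))
  if (k < 2L) stop("too few complete cases per class for cross-validation")
  fold <- make_folds(y, k, derive_seed(seed, 1L))
  all_cells <- seq_len(n_cells(stack$grid))
  X_grid <- build_design(stack, all_cells)
  grid_ok <- stats::complete.cases(X_grid)

  aucs <- numeric(length(learners)); names(aucs) <- names(learners)
  full_pred <- matrix(NA_real_, length(all_cells), length(learners),
                      dimnames = list(NULL, names(learners)))
  train_pred <- matrix(NA_real_, length(y), length(learners),
                       dimnames = list(NULL, names(learners)))
  for (m in seq_along(learners)) {
    L <- learners[[m]]
    fold_auc <- numeric(k)
    for (f in seq_len(k)) {
      tr <- fold != f; te <- fold == f
      if (length(unique(y[te])) < 2L || length(unique(y[tr])) < 2L)
        stop("degenerate single-class fold despite stratification")
      model <- with_seed(derive_seed(seed, 100L + 10L * m + f),
                         L$fit(X[tr, , drop = FALSE], y[tr]))
      fold_auc[f] <- auc(y[te], L$predict(model, X[te, , drop = FALSE]))
    }
    aucs[m] <- mean(fold_auc)
    model <- with_seed(derive_seed(seed, 200L + m),
                       L$fit(X, y))
    train_pred[, m] <- L$predict(model, X)
    full_pred[grid_ok, m] <- L$predict(model, X_grid[grid_ok, , drop = FALSE])
  }
  w <- ifelse(aucs > auc_cutoff, aucs, 0)
  usable <- any(w > 0)
  consensus <- empty_layer(stack$grid, NA_real_)
  scores <- rep(NA_real_, length(y))
  if (usable) {
    cv <- as.vector(full_pred[, w > 0, drop = FALSE] %*% w[w > 0] / sum(w))
    consensus <- matrix(NA_real_, stack$grid$n_rows, stack$grid$n_cols)
    consensus <- `layer_values<-`(consensus, all_cells, cv)
    scores <- as.vector(train_pred[, w > 0, drop = FALSE] %*% w[w > 0] / sum(w))
  }
  learner_layers <- lapply(seq_along(learners), function(m) {
    lay <- matrix(NA_real_, stack$grid$n_rows, stack$grid$n_cols)
    `layer_values<-`(lay, all_cells, full_pred[, m])
  })
  names(learner_layers) <- names(learners)
  structure(list(auc = aucs, weights = w, auc_cutoff = auc_cutoff,
                 consensus = consensus, learner_layers = learner_layers,
                 scores = scores, labels = y,
                 cells = cells, folds = k, usable = usable),
            class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat("ensemble_result:",
      paste(sprintf("%s AUC=%.3f", names(x$auc), x$auc), collapse = ", "),
      if (x$usable) "" else "(UNUSABLE: no learner above cutoff)", "\n")
  invisible(x)
}

#' Commission-minimizing suitability threshold
#'
#' Computes four candidate thresholds over the sorted unique scores — (a) the
#' largest threshold keeping sensitivity at or above `sensitivity_floor`
#' (minimal-predicted-area criterion), (b) maximum overall accuracy, (c)
#' maximum Cohen's kappa, (d) maximum TSS — and returns the largest of the
#' four, which minimizes commission error. Argmax ties resolve to the larger
#' threshold. If the returned threshold classifies the data perfectly it is
#' replaced by the midpoint of the separating gap (documented degenerate-case
#' convention).
#'
#' @param labels 0/1 vector (both classes present).
#' @param scores Numeric suitability scores; a cell is predicted present when
#'   its score is `>=` the threshold.
#' @param sensitivity_floor Sensitivity floor for criterion (a), default 0.9.
#' @return List: `threshold`, `criterion` (which of the four produced it) and
#'   the four `candidates`.
#' @export
select_threshold <- function(labels, scores, sensitivity_floor = 0.9) {
  labels <- as.integer(labels)
  np <- sum(labels == 1L); nn <- sum(labels == 0L)
  if (np == 0L || nn == 0L) stop("threshold selection requires both classes")
  cand <- sort(unique(scores))
  stats_at <- function(th) {
    pred <- scores >= th
    tp <- sum(pred & labels == 1L); fn <- np - tp
    fp <- sum(pred & labels == 0L); tn <- nn - fp
    sens <- tp / np; spec <- tn / nn
    acc <- (tp + tn) / (np + nn)
    pe <- ((tp + fp) * np + (fn + tn) * nn) / (np + nn)^2
    kappa <- if (abs(1 - pe) < 1e-12) 0 else (acc - pe) / (1 - pe)
    c(sens = sens, spec = spec, acc = acc, kappa = kappa, tss = sens + spec - 1)
  }
  st <- t(vapply(cand, stats_at, numeric(5)))
  pick_max <- function(metric) cand[max(which(st[, metric] == max(st[, metric])))]
  sens_ok <- which(st[, "sens"] >= sensitivity_floor)
  cands <- c(sensitivity_floor = if (length(sens_ok)) cand[max(sens_ok)] else min(cand),
             max_accuracy = pick_max("acc"),
             max_kappa = pick_max("kappa"),
             max_tss = pick_max("tss"))
  th <- max(cands)
  criterion <- names(cands)[max(which(cands == th))]
  # degenerate case: perfect separation -> midpoint of the separating gap
  s <- stats_at(th)
  if (s["sens"] == 1 && s["spec"] == 1) {
    below <- scores[scores < th]
    if (length(below)) {
      th <- (th + max(below)) / 2
      criterion <- paste0(criterion, " (separating-gap midpoint)")
    }
  }
  list(threshold = unname(th), criterion = criterion, candidates = cands)
}

#' Binarize a suitability layer with record override
#'
#' A cell is predicted present when its suitability reaches the threshold;
#' cells holding occurrence records are presences regardless of the model.
#'
#' @param HS Consensus suitability layer (matrix).
#' @param threshold Threshold in `[0, 1]`.
#' @param record_cells Integer ids of record cells.
#' @return Binary 0/1 matrix.
#' @export
binarize_with_override <- function(HS, threshold, record_cells = integer(0)) {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  out <- (!is.na(HS) & HS >= threshold) * 1L
  if (length(record_cells)) out <- `layer_values<-`(out, record_cells, 1L)
  out
}

# 8-connected component labels of a binary matrix; 0 = background
label_components <- function(binary) {
  nr <- nrow(binary); nc <- ncol(binary)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  offs <- cbind(rep(-1:1, 3), rep(-1:1, each = 3))
  offs <- offs[!(offs[, 1] == 0 & offs[, 2] == 0), ]
  for (start in which(binary == 1L)) {
    if (lab[start] > 0L) next
    cur <- cur + 1L
    stack <- start
    lab[start] <- cur
    while (length(stack)) {
      pos <- stack[length(stack)]; stack <- stack[-length(stack)]
      r <- (pos - 1L) %% nr + 1L; cc <- (pos - 1L) %/% nr + 1L
      nb_r <- r + offs[, 1]; nb_c <- cc + offs[, 2]
      okn <- nb_r >= 1L & nb_r <= nr & nb_c >= 1L & nb_c <= nc
      nb <- (nb_c[okn] - 1L) * nr + nb_r[okn]
      nb <- nb[binary[nb] == 1L & lab[nb] == 0L]
      if (length(nb)) { lab[nb] <- cur; stack <- c(stack, nb) }
    }
  }
  lab
}

#' Mean nearest-neighbour distance between records
#'
#' For each record, the Euclidean distance (degrees) to its nearest other
#' record; the mean of these defines the barrier width `d_bar`. A single
#' record gives 0.
#'
#' @param xy Two-column matrix of record coordinates.
#' @return Mean nearest-neighbour distance.
#' @export
mean_nn_distance <- function(xy) {
  n <- nrow(xy)
  if (n < 2L) return(0)
  d <- as.matrix(stats::dist(xy))
  diag(d) <- Inf
  mean(apply(d, 1L, min))
}

#' Clip a binary range to record-anchored components
#'
#' Labels 8-connected components of the binary layer, keeps every component
#' containing at least one record cell, and keeps a recordless component only
#' if its minimum cell-centre distance to any record-containing component is
#' at most the mean nearest-neighbour distance between records (`d_bar`).
#' Everything else — habitat isolated from the known range by a barrier of
#' unsuitable cells wider than `d_bar` — is set to 0. Record cells always
#' survive. With a single record `d_bar = 0`, so only its component remains;
#' species below the modelling minimum are handled upstream by treating the
#' unique occupied cell as the entire distribution.
#'
#' @param binary Binary 0/1 layer (after record override).
#' @param records_xy Two-column matrix of record coordinates (>= 1 row).
#' @param spec The layer's `grid_spec`.
#' @param chain If `TRUE`, iterate retention to a fixpoint so recordless
#'   components can be kept through other retained recordless components;
#'   default is the single-pass rule.
#' @return A `species_range`: `layer` (binary), `record_cells`, `components`
#'   (label matrix), `d_bar`.
#' @export
barrier_clip <- function(binary, records_xy, spec, chain = FALSE) {
  if (is.null(dim(records_xy))) records_xy <- matrix(records_xy, ncol = 2)
  if (nrow(records_xy) < 1L) stop("barrier_clip requires at least one record")
  record_cells <- unique(point_to_cell(spec, records_xy[, 1], records_xy[, 2]))
  record_cells <- record_cells[!is.na(record_cells)]
  if (!length(record_cells)) stop("no record falls inside the grid extent")
  binary <- `layer_values<-`(binary, record_cells, 1L)
  d_bar <- mean_nn_distance(records_xy)
  lab <- label_components(binary)
  rec_lab <- unique(layer_values(lab, record_cells))
  comps <- setdiff(unique(lab[lab > 0L]), 0L)
  keep <- comps[comps %in% rec_lab]
  others <- setdiff(comps, keep)
  if (length(others)) {
    ctr_all <- cell_centres(spec)
    comp_cells <- function(ids) {
      sel <- lab %in% ids
      layer_which(lab, sel)
    }
    anchor_xy <- ctr_all[comp_cells(keep), , drop = FALSE]
    repeat {
      added <- integer(0)
      for (cmp in others) {
        xy <- ctr_all[comp_cells(cmp), , drop = FALSE]
        dmin <- min(vapply(seq_len(nrow(xy)), function(i)
          min(sqrt((anchor_xy[, 1] - xy[i, 1])^2 + (anchor_xy[, 2] - xy[i, 2])^2)),
          numeric(1)))
        if (dmin <= d_bar) added <- c(added, cmp)
      }
      keep <- c(keep, added)
      others <- setdiff(others, added)
      if (!chain || !length(added) || !length(others)) break
      anchor_xy <- ctr_all[comp_cells(keep), , drop = FALSE]
    }
  }
  out <- (lab %in% keep & binary == 1L) * 1L
  dim(out) <- dim(binary)
  structure(list(layer = out, record_cells = sort(record_cells),
                 components = lab, d_bar = d_bar),
            class = "species_range")
}

#' Build one species' range: model, threshold, override, clip
#'
#' Orchestrates the per-species stages: presence cells from records;
#' pseudo-absence sampling; ensemble fit; commission-minimizing threshold on
#' the consensus scores; binarization with record override; barrier clipping.
#' Species with fewer than `min_records_for_model` records bypass modelling:
#' their occupied cells are the entire distribution.
#'
#' @param stack Screened `predictor_stack`.
#' @param records_xy Two-column matrix of this species' record coordinates.
#' @param n_pseudo_absences Background sample size (500 coarse / 200 fine by
#'   convention).
#' @param learners Named list of learners.
#' @param folds Cross-validation folds.
#' @param seed Integer seed.
#' @param auc_cutoff Consensus weight cutoff.
#' @param sensitivity_floor Sensitivity floor for threshold criterion (a).
#' @param min_records_for_model Below this record count, skip modelling
#'   (default 2).
#' @return List: `range` (a `species_range`), `ensemble` (or `NULL`),
#'   `threshold` info (or `NULL`), `modelled` flag.
#' @export
build_species_range <- function(stack, records_xy, n_pseudo_absences,
                                learners = default_learners(), folds = 10L,
                                seed = 1L, auc_cutoff = 0.7,
                                sensitivity_floor = 0.9,
                                min_records_for_model = 2L) {
  if (is.null(dim(records_xy))) records_xy <- matrix(records_xy, ncol = 2)
  spec <- stack$grid
  presence_cells <- unique(point_to_cell(spec, records_xy[, 1], records_xy[, 2]))
  presence_cells <- sort(presence_cells[!is.na(presence_cells)])
  if (!length(presence_cells)) stop("no record falls inside the grid extent")
  if (nrow(records_xy) < min_records_for_model || length(presence_cells) < 2L) {
    lay <- empty_layer(spec, 0L)
    lay <- `layer_values<-`(lay, presence_cells, 1L)
    rng <- structure(list(layer = lay, record_cells = presence_cells,
                          components = lay, d_bar = 0),
                     class = "species_range")
    return(list(range = rng, ensemble = NULL, threshold = NULL, modelled = FALSE))
  }
  pa <- sample_pseudo_absences(spec, presence_cells, n_pseudo_absences,
                               derive_seed(seed, 11L))
  ens <- fit_ensemble(stack, presence_cells, pa, learners = learners,
                      folds = folds, seed = derive_seed(seed, 12L),
                      auc_cutoff = auc_cutoff)
  if (!ens$usable) {
    # no learner beat the cutoff: fall back to the record cells alone
    lay <- empty_layer(spec, 0L)
    lay <- `layer_values<-`(lay, presence_cells, 1L)
    rng <- structure(list(layer = lay, record_cells = presence_cells,
                          components = lay, d_bar = mean_nn_distance(records_xy)),
                     class = "species_range")
    return(list(range = rng, ensemble = ens, threshold = NULL, modelled = FALSE))
  }
  th <- select_threshold(ens$labels, ens$scores, sensitivity_floor)
  bin <- binarize_with_override(ens$consensus, min(max(th$threshold, 0), 1), presence_cells)
  rng <- barrier_clip(bin, records_xy, spec)
  list(range = rng, ensemble = ens, threshold = th, modelled = TRUE)
}
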