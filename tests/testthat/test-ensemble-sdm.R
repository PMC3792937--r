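test_that("pseudo-absence sampling: forced outcome, determinism, deficit error", {
  sp <- grid_spec(0, 10, 1, 10, 10)
  # presence everywhere except 10 cells -> exactly those 10
  free <- c(3, 17, 25, 44, 51, 62, 70, 81, 90, 99)
  pres <- setdiff(1:100, free)
  expect_equal(sample_pseudo_absences(sp, pres, 10, seed = 1), sort(free))
  # fixed seed -> identical draws; disjoint from presences
  a <- sample_pseudo_absences(sp, 1:20, 30, seed = 42)
  b <- sample_pseudo_absences(sp, 1:20, 30, seed = 42)
  expect_identical(a, b)
  expect_length(intersect(a, 1:20), 0)
  expect_length(unique(a), 30)
  expect_error(sample_pseudo_absences(sp, 1:95, 10, seed = 1), "deficit")
})

test_that("auc is the Mann-Whitney probability with ties at one half", {
  expect_equal(auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1.0)
  expect_equal(auc(c(1, 0), c(0.4, 0.4)), 0.5)
  expect_error(auc(c(1, 1), c(0.2, 0.3)), "both classes")
  # exact U-statistic oracle on random data
  set.seed(9)
  for (i in 1:5) {
    y <- rbinom(60, 1, 0.4)
    if (length(unique(y)) < 2) next
    s <- rnorm(60)
    U <- unname(wilcox.test(s[y == 1], s[y == 0], exact = FALSE)$statistic)
    expect_equal(auc(y, s), U / (sum(y == 1) * sum(y == 0)), tolerance = 1e-12)
  }
  # Monte-Carlo: random scores give AUC near 0.5 (scaled from the 500-rep case)
  set.seed(10)
  m <- mean(replicate(200, auc(rep(c(1, 0), each = 500), runif(1000))))
  expect_lt(abs(m - 0.5), 0.02)
})

test_that("threshold selection implements the four criteria and the max rule", {
  # criterion (a) alone: 10 presences scored 0.1..1.0, floor 0.9 -> 0.2
  scores <- c(seq(0.1, 1, by = 0.1), rep(0.05, 5))
  labels <- c(rep(1, 10), rep(0, 5))
  th <- select_threshold(labels, scores, sensitivity_floor = 0.9)
  expect_equal(unname(th$candidates["sensitivity_floor"]), 0.2)
  # returned threshold is always the max of the four candidates
  expect_equal(th$threshold, max(th$candidates))
  set.seed(21)
  for (i in 1:10) {
    y <- rep(c(1, 0), times = c(15, 25))
    s <- runif(40)
    res <- select_threshold(y, s)
    expect_gte(res$threshold, max(res$candidates) - 1e-12)
  }
  # perfectly separated scores -> midpoint of the separating gap
  y <- c(1, 1, 1, 0, 0)
  s <- c(0.8, 0.9, 1.0, 0.1, 0.2)
  res <- select_threshold(y, s)
  expect_equal(res$threshold, (0.8 + 0.2) / 2)
  expect_match(res$criterion, "separating-gap midpoint")
})

test_that("binarize_with_override: record override and monotone shrinkage", {
  HS <- matrix(runif(100), 10, 10)
  HS[1, 1] <- 0
  rec <- c(1L, 55L)
  b <- binarize_with_override(HS, 0.5, rec)
  expect_equal(b[1, 1], 1L)                 # record cell with HS = 0 is present
  expect_true(all(binarize_with_override(HS, 0, integer(0)) == 1L))
  HS2 <- pmin(HS, 0.999)
  expect_true(all(binarize_with_override(HS2, 1, integer(0)) == 0L))
  # raising the threshold never adds cells (record cells excepted)
  prev <- binarize_with_override(HS, 0.2, rec)
  for (th in c(0.4, 0.6, 0.8)) {
    cur <- binarize_with_override(HS, th, rec)
    expect_true(all(cur <= prev))
    prev <- cur
  }
  expect_error(binarize_with_override(HS, 1.5), "0, 1")
})

test_that("barrier_clip keeps record components and near recordless patches only", {
  sp <- tiny_spec(20L)                     # 20x20, cell size 1, top-left (0,20)
  bin <- matrix(0L, 20, 20)
  bin[10, 1:9] <- 1L                       # patch A (records)
  bin[10, 12:13] <- 1L                     # patch B, gap 2 cells (centre dist 3)
  bin[10, 19:20] <- 1L                     # patch C, gap 5 cells (centre dist 6)
  # records at centres of cells (10, 2), (10, 5), (10, 8): NN distances 3,3,3
  rec <- cell_centres(sp, point_to_cell(sp, c(1.5, 4.5, 7.5), rep(10.5, 3)))
  out <- barrier_clip(bin, rec, sp)
  expect_equal(out$d_bar, 3)
  expect_true(all(out$layer[10, 1:9] == 1L))
  expect_true(all(out$layer[10, 12:13] == 1L))   # gap 2 <= d_bar: retained
  expect_true(all(out$layer[10, 19:20] == 0L))   # gap 5 > d_bar: removed
  # records in both patches -> both retained regardless of gap
  rec2 <- rbind(rec, cell_centres(sp, point_to_cell(sp, 19.5, 10.5)))
  out2 <- barrier_clip(bin, rec2, sp)
  expect_true(all(out2$layer[10, 19:20] == 1L))
  # single record: exactly the occupied cell
  out1 <- barrier_clip(matrix(0L, 20, 20), cbind(3.5, 10.5), sp)
  expect_equal(sum(out1$layer), 1)
  expect_equal(out1$d_bar, 0)
  expect_error(barrier_clip(bin, rec[0, , drop = FALSE], sp), "at least one record")
})

test_that("ensemble: consensus equals the weighted average of passing learners", {
  set.seed(30)
  sp <- grid_spec(0, 12, 1, 12, 12)
  x1 <- matrix(rnorm(144), 12, 12)
  x2 <- matrix(rnorm(144), 12, 12)
  st <- predictor_stack(sp, list(x1 = x1, x2 = x2))
  # response driven by x1: strong signal
  score <- as.vector(t(x1))               # row-major, like cell ids
  pres <- order(score, decreasing = TRUE)[1:25]
  abs_ <- sample(setdiff(1:144, pres), 60)
  good <- sdm_learner("good",
                      fit = function(X, y) NULL,
                      predict = function(model, X) plogis(3 * X[, "x1"]))
  anti <- sdm_learner("anti",
                      fit = function(X, y) NULL,
                      predict = function(model, X) plogis(-3 * X[, "x1"]))
  ens <- fit_ensemble(st, pres, abs_, learners = list(good = good, anti = anti),
                      folds = 5, seed = 1)
  expect_gt(ens$auc[["good"]], 0.95)
  expect_equal(unname(ens$weights[["anti"]]), 0)   # AUC below cutoff: weight 0
  # single passing learner: consensus equals its prediction exactly
  expect_equal(ens$consensus, ens$learner_layers$good, tolerance = 1e-12)
  # two passing learners: consensus is the AUC-weighted mean, bounded per cell
  good2 <- sdm_learner("good2",
                       fit = function(X, y) NULL,
                       predict = function(model, X) plogis(2 * X[, "x1"] + 0.3 * X[, "x2"]))
  ens2 <- fit_ensemble(st, pres, abs_, learners = list(g1 = good, g2 = good2),
                       folds = 5, seed = 1)
  expect_true(all(ens2$weights > 0.7))
  w <- ens2$weights
  manual <- (w[["g1"]] * ens2$learner_layers$g1 + w[["g2"]] * ens2$learner_layers$g2) / sum(w)
  expect_equal(ens2$consensus, manual, tolerance = 1e-12)
  lo <- pmin(ens2$learner_layers$g1, ens2$learner_layers$g2)
  hi <- pmax(ens2$learner_layers$g1, ens2$learner_layers$g2)
  expect_true(all(ens2$consensus >= lo - 1e-12 & ens2$consensus <= hi + 1e-12))
})

test_that("ensemble flags unusable when no learner beats the cutoff", {
  set.seed(31)
  sp <- grid_spec(0, 10, 1, 10, 10)
  st <- predictor_stack(sp, list(x1 = matrix(rnorm(100), 10, 10)))
  coin <- sdm_learner("coin", fit = function(X, y) NULL,
                      predict = function(model, X) rep(0.5, nrow(X)))
  pres <- sample(1:100, 20)
  ens <- fit_ensemble(st, pres, setdiff(1:100, pres)[1:40],
                      learners = list(coin = coin), folds = 4, seed = 2)
  expect_false(ens$usable)
  expect_equal(unname(ens$weights), 0)
})

test_that("shipped learners recover a strong synthetic signal (seeded soft property)", {
  w <- make_world(3, grid_spec(10, 0, 0.25, 48, 48), k = 4, n_species = 2,
                  n_predictors = 4, records_per_species = c(60L, 80L),
                  reserve_fraction = 0)
  st <- vif_screen(w$predictors)
  aucs <- c(); jac <- c()
  for (sp in names(w$true_range)) {
    xy <- as.matrix(w$records[w$records$species == sp, c("lon", "lat")])
    res <- build_species_range(st, xy, n_pseudo_absences = 200, seed = 9)
    aucs <- c(aucs, res$ensemble$auc)
    tr <- w$true_range[[sp]]
    jac <- c(jac, sum(res$range$layer == 1 & tr == 1) / sum(res$range$layer == 1 | tr == 1))
    # clip output is a subset of the binarized layer plus record cells
    bin <- binarize_with_override(res$ensemble$consensus, res$threshold$threshold,
                                  res$range$record_cells)
    expect_true(all(res$range$layer <= bin))
    rc <- res$range$record_cells
    rcv <- vapply(rc, function(id) {
      r <- (id - 1) %/% 48 + 1; cc <- (id - 1) %% 48 + 1
      res$range$layer[r, cc]
    }, numeric(1))
    expect_true(all(rcv == 1))            # record cells always survive
  }
  expect_gt(median(aucs), 0.8)
  expect_gt(min(jac), 0.3)
})
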