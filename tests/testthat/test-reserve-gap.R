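test_that("coverage_threshold minimizes the area mismatch over candidate thresholds", {
  # brute-force worked case: {0, .2, .5, .9}, cell area 1, reserve area 1.6
  res <- coverage_threshold(c(0, 0.2, 0.5, 0.9), 1, 1.6)
  expect_equal(res$threshold, 0.2)
  expect_equal(res$n_selected, 2L)
  # the choice is optimal among all candidate thresholds (derived brute force)
  set.seed(50)
  for (i in 1:10) {
    v <- runif(30)
    A <- runif(1, 0, 30)
    got <- coverage_threshold(v, 1, A)
    errs <- vapply(sort(unique(v)), function(th) abs(sum(v > th) - A), numeric(1))
    expect_equal(abs(got$n_selected - A), min(errs), tolerance = 1e-12)
  }
})

test_that("reserves covering whole cells are selected exactly (10 seeded cases)", {
  for (seed in 1:10) {
    w <- small_world(seed = seed, n = 24L, k = 2L, n_species = 2L,
                     records = c(3L, 5L), fraction = runif(1, 0.05, 0.3))
    cov <- reserve_coverage(w$fine_spec, w$reserves)
    # synthetic reserves are cell-aligned: coverage is 0/1
    expect_true(all(abs(cov) < 1e-9 | abs(cov - 1) < 1e-9))
    m <- sum(cov > 0.5)
    thr <- coverage_threshold(cov, w$fine_spec$cell_size^2, w$reserve_area)
    expect_equal(length(protected_cells(cov, thr$threshold)), m)
  }
})

test_that("polygon coverage matches a fine rasterization oracle for a triangle", {
  sp <- grid_spec(0, 10, 1, 10, 10)
  tri <- cbind(c(1.2, 7.8, 3.1), c(2.3, 3.7, 8.9))
  cov <- reserve_coverage(sp, list(tri))
  expect_equal(sum(cov), polygon_area(tri), tolerance = 1e-9)  # exact clipping
  # per-cell check against point-in-polygon sampling on a 20x finer lattice
  sub <- 20L
  inside_tri <- function(px, py) {
    n <- nrow(tri); inside <- rep(FALSE, length(px))
    j <- n
    for (i in seq_len(n)) {
      xi <- tri[i, 1]; yi <- tri[i, 2]; xj <- tri[j, 1]; yj <- tri[j, 2]
      cross <- (yi > py) != (yj > py) & px < (xj - xi) * (py - yi) / (yj - yi) + xi
      inside <- xor(inside, cross)
      j <- i
    }
    inside
  }
  for (cell in c(23L, 34L, 45L, 56L)) {
    r <- (cell - 1) %/% 10 + 1; cc <- (cell - 1) %% 10 + 1
    gx <- (cc - 1) + (seq_len(sub) - 0.5) / sub
    gy <- (10 - r) + (seq_len(sub) - 0.5) / sub
    pts <- expand.grid(x = gx, y = gy)
    expect_equal(cov[r, cc], mean(inside_tri(pts$x, pts$y)), tolerance = 0.05)
  }
})

test_that("set_targets interpolates log-linearly with nearest-integer rounding", {
  # 100% at the smallest range, 5% at the largest
  t <- set_targets(c(1, 1082))
  expect_equal(unname(t), c(1L, 54L))
  # scale-monotone: larger ranges get weakly smaller target percentages
  r <- c(1, 5, 24, 44, 56, 66, 77, 85, 122, 137, 156, 212, 343, 644, 661, 1082)
  tt <- set_targets(r)
  pct <- 100 * tt / r
  expect_true(all(diff(pct) <= 1e-9))
  expect_true(all(tt >= 1 & tt <= r))
  # degenerate single-species input gets the smallest-range percentage
  expect_equal(unname(set_targets(40)), 40L)
  expect_error(set_targets(numeric(0)), "non-empty")
  expect_error(set_targets(c(0, 10)), ">= 1")
})

test_that("gap_analysis classifies species and computes capped percentages", {
  # hand count: |R| = 10, 4 protected, t = 8 -> 40% protected, 50% met, partial
  rep1 <- gap_analysis(list(sp1 = 1:10), protected = c(1:4, 90:99), targets = 8L)
  expect_equal(rep1$pct_range_protected, 40)
  expect_equal(rep1$pct_target_met, 50)
  expect_equal(rep1$gap_class, "partial gap")
  expect_false(rep1$target_exceeded)
  # zero overlap -> total gap with 0.00% met
  rep2 <- gap_analysis(list(sp = 1:5), protected = 11:20, targets = 2L)
  expect_equal(rep2$gap_class, "total gap")
  expect_equal(rep2$pct_target_met, 0)
  # over-achieved target -> met, capped at 100 and flagged (the dash)
  rep3 <- gap_analysis(list(sp = 1:10), protected = 1:9, targets = 3L)
  expect_equal(rep3$gap_class, "met")
  expect_equal(rep3$pct_target_met, 100)
  expect_true(rep3$target_exceeded)
  expect_error(gap_analysis(list(sp = integer(0)), 1:2, 1L), "non-empty")
})

test_that("gap rules on synthetic worlds: total-gap and reserve-growth monotonicity", {
  for (seed in 1:20) {
    w <- small_world(seed = seed, n = 24L, k = 2L, n_species = 3L,
                     records = c(1L, 4L, 6L), fraction = 0.1)
    sets <- lapply(w$true_range, function(r) layer_which(r, r == 1L))
    targets <- set_targets(lengths(sets))
    cov <- reserve_coverage(w$fine_spec, w$reserves)
    thr <- coverage_threshold(cov, w$fine_spec$cell_size^2, w$reserve_area)
    prot <- protected_cells(cov, thr$threshold)
    rep0 <- gap_analysis(sets, prot, targets)
    zero <- rep0$pct_range_protected == 0
    expect_true(all(rep0$gap_class[zero] == "total gap"))
    expect_true(all(rep0$gap_class[!zero] != "total gap"))
    # enlarging the reserve set never lowers % target met or demotes a class
    extra <- union(prot, sample(seq_len(24 * 24), 50))
    rep1 <- gap_analysis(sets, extra, targets)
    expect_true(all(rep1$pct_target_met >= rep0$pct_target_met - 1e-12))
    expect_true(all(!(rep0$gap_class == "met" & rep1$gap_class != "met")))
  }
})

test_that("gap analysis on true ranges recovers ground-truth protection exactly", {
  w <- small_world(seed = 33, n = 24L, k = 2L, n_species = 4L,
                   records = c(1L, 4L, 6L, 8L), fraction = 0.15)
  tm <- true_metrics(w)
  sets <- lapply(w$true_range, function(r) layer_which(r, r == 1L))
  cov <- reserve_coverage(w$fine_spec, w$reserves)
  thr <- coverage_threshold(cov, w$fine_spec$cell_size^2, w$reserve_area)
  rep <- gap_analysis(sets, protected_cells(cov, thr$threshold),
                      set_targets(lengths(sets)))
  expect_equal(rep$pct_range_protected / 100, tm$true_protected_fraction,
               tolerance = 1e-9)
})

test_that("gap reports write the dash convention to CSV", {
  rep <- gap_analysis(list(a = 1:10, b = 11:15), protected = c(1:9, 11),
                      targets = c(3L, 4L))
  f <- tempfile(fileext = ".csv")
  write_gap_csv(rep, f)
  back <- utils::read.csv(f, stringsAsFactors = FALSE, colClasses = "character")
  expect_equal(back$pct_target_met[1], "")      # over-achieved -> empty cell
  expect_equal(back$target_exceeded, c("TRUE", "FALSE"))
  unlink(f)
})
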