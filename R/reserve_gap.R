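# Sutherland-Hodgman clip of a simple polygon against an axis-aligned box;
# the box is convex so the clipped result is a single polygon
clip_polygon_box <- function(poly, xmin, xmax, ymin, ymax) {
  clip_edge <- function(pts, inside, intersect) {
    if (!nrow(pts)) return(pts)
    out <- matrix(numeric(0), ncol = 2)
    n <- nrow(pts)
    for (i in seq_len(n)) {
      cur <- pts[i, ]; prv <- pts[if (i == 1L) n else i - 1L, ]
      ci <- inside(cur); pi <- inside(prv)
      if (ci) {
        if (!pi) out <- rbind(out, intersect(prv, cur))
        out <- rbind(out, cur)
      } else if (pi) {
        out <- rbind(out, intersect(prv, cur))
      }
    }
    out
  }
  ix <- function(p, q, val, coord) {
    t <- (val - p[coord]) / (q[coord] - p[coord])
    p + t * (q - p)
  }
  pts <- poly
  pts <- clip_edge(pts, function(p) p[1] >= xmin, function(p, q) ix(p, q, xmin, 1))
  pts <- clip_edge(pts, function(p) p[1] <= xmax, function(p, q) ix(p, q, xmax, 1))
  pts <- clip_edge(pts, function(p) p[2] >= ymin, function(p, q) ix(p, q, ymin, 2))
  pts <- clip_edge(pts, function(p) p[2] <= ymax, function(p, q) ix(p, q, ymax, 2))
  pts
}

#' Per-cell reserve coverage fractions
#'
#' Exact fraction of each cell's area intersected by the reserve polygons
#' (assumed mutually disjoint, as produced by [make_world()]; overlapping
#' reserves would double-count).
#'
#' @param spec A `grid_spec`.
#' @param reserves List of polygon vertex matrices.
#' @return Matrix of coverage fractions in `[0, 1]`.
#' @export
reserve_coverage <- function(spec, reserves) {
  s <- spec$cell_size
  cov <- matrix(0, spec$n_rows, spec$n_cols)
  for (poly in reserves) {
    xr <- range(poly[, 1]); yr <- range(poly[, 2])
    c0 <- max(1L, floor((xr[1] - spec$origin_lon) / s) + 1L)
    c1 <- min(spec$n_cols, ceiling((xr[2] - spec$origin_lon) / s))
    r0 <- max(1L, floor((spec$origin_lat - yr[2]) / s) + 1L)
    r1 <- min(spec$n_rows, ceiling((spec$origin_lat - yr[1]) / s))
    if (c1 < c0 || r1 < r0) next
    for (r in r0:r1) for (cc in c0:c1) {
      xmin <- spec$origin_lon + (cc - 1L) * s
      ymax <- spec$origin_lat - (r - 1L) * s
      clp <- clip_polygon_box(poly, xmin, xmin + s, ymax - s, ymax)
      if (nrow(clp) >= 3L) cov[r, cc] <- cov[r, cc] + polygon_area(clp) / s^2
    }
  }
  pmin(cov, 1)
}

#' Area-matching coverage threshold for protected cells
#'
#' A cell counts as protected when its reserve-coverage fraction is strictly
#' larger than the threshold. Among candidate thresholds (the sorted unique
#' coverage values) this picks the one whose selected-cell surface is closest
#' to the true total reserve surface; ties go to the larger threshold.
#'
#' @param coverage Coverage fractions (matrix or vector) in `[0, 1]`.
#' @param cell_area Area of one cell.
#' @param total_reserve_area Total reserve surface, same units.
#' @return List: `threshold`, `n_selected`, `area_error`.
#' @export
coverage_threshold <- function(coverage, cell_area, total_reserve_area) {
  v <- as.numeric(coverage)
  if (any(v < 0 | v > 1, na.rm = TRUE)) stop("coverage fractions must be in [0, 1]")
  if (total_reserve_area < 0) stop("total_reserve_area must be >= 0")
  cand <- sort(unique(v[!is.na(v)]))
  n_sel <- vapply(cand, function(th) sum(v > th, na.rm = TRUE), numeric(1))
  err <- abs(n_sel * cell_area - total_reserve_area)
  best <- max(which(err == min(err)))           # ties -> larger threshold
  list(threshold = cand[best], n_selected = as.integer(n_sel[best]),
       area_error = err[best])
}

#' Protected cell ids from a coverage layer
#' @param coverage Coverage-fraction matrix.
#' @param threshold Threshold from [coverage_threshold()].
#' @return Sorted integer cell ids with coverage strictly above the threshold.
#' @export
protected_cells <- function(coverage, threshold) {
  layer_which(coverage, !is.na(coverage) & coverage > threshold)
}

#' Range-scaled conservation targets
#'
#' The target percentage is 100% of the range for the smallest-ranged species
#' and 5% for the most widespread, interpolated linearly in log range size
#' between those extremes; the cell target is the percentage of the range,
#' rounded to the nearest integer and clamped to `[1, range]`.
#'
#' @param range_sizes Per-species range sizes in cells (>= 1); names carried
#'   through.
#' @param pct_smallest Target percentage at the minimum range (default 100).
#' @param pct_largest Target percentage at the maximum range (default 5).
#' @return Integer targets, named like `range_sizes`.
#' @export
set_targets <- function(range_sizes, pct_smallest = 100, pct_largest = 5) {
  if (!length(range_sizes)) stop("range_sizes must be non-empty")
  if (any(range_sizes < 1)) stop("range sizes must be >= 1")
  r <- as.numeric(range_sizes)
  rmin <- min(r); rmax <- max(r)
  pct <- if (rmax == rmin) rep(pct_smallest, length(r)) else
    pct_smallest + (pct_largest - pct_smallest) * (log(r) - log(rmin)) / (log(rmax) - log(rmin))
  t <- round(pct / 100 * r)
  t <- pmin(pmax(t, 1), r)
  stats::setNames(as.integer(t), names(range_sizes))
}

#' Gap analysis of species representation in reserves
#'
#' For each species: protected range cells, percent of range protected,
#' percent of target met (capped at 100 with the cap flagged, mirroring the
#' dash convention for over-achieved targets), and a gap class — `total gap`
#' (no protected range cells), `partial gap` (some, target unmet) or `met`
#' (protected cells reach the target).
#'
#' @param range_sets Named list of per-species cell-id vectors (non-empty).
#' @param protected Integer ids of protected cells.
#' @param targets Per-species integer targets (same order/names).
#' @return A `gap_report` data frame: `species`, `range_cells`,
#'   `pct_range_protected`, `target`, `pct_target_met`, `target_exceeded`,
#'   `gap_class`.
#' @export
gap_analysis <- function(range_sets, protected, targets) {
  if (any(lengths(range_sets) == 0L)) stop("every species must have a non-empty range")
  targets <- check_targets(range_sets, targets)
  sp <- if (is.null(names(range_sets))) sprintf("species_%02d", seq_along(range_sets)) else names(range_sets)
  p <- vapply(range_sets, function(R) length(intersect(R, protected)), integer(1))
  sz <- lengths(range_sets)
  pct_prot <- 100 * p / sz
  raw_met <- 100 * p / targets
  out <- data.frame(
    species = sp,
    range_cells = as.integer(sz),
    pct_range_protected = pct_prot,
    target = targets,
    pct_target_met = pmin(raw_met, 100),
    target_exceeded = raw_met > 100,
    gap_class = ifelse(p == 0L, "total gap", ifelse(p >= targets, "met", "partial gap")),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("gap_report", "data.frame")
  out
}

#' Write a gap report as CSV
#'
#' Mirrors the classic target-table layout; over-achieved target percentages
#' are encoded as an empty cell plus the `target_exceeded` flag column.
#'
#' @param report A `gap_report`.
#' @param path Output CSV path.
#' @export
write_gap_csv <- function(report, path) {
  out <- report
  out$pct_target_met <- ifelse(out$target_exceeded, "",
                               sprintf("%.2f", out$pct_target_met))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
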