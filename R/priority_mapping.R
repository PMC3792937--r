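#' Species richness layer
#'
#' Per-cell count of species whose binary range contains the cell.
#'
#' @param ranges List of binary 0/1 matrices on a shared grid.
#' @return Integer matrix of counts (all zeros for an empty list of known
#'   dimensions is not constructible; pass at least one layer or use
#'   `empty_layer`).
#' @export
richness <- function(ranges) {
  if (!length(ranges)) stop("richness requires at least one range layer")
  d <- dim(ranges[[1]])
  for (r in ranges) if (!identical(dim(r), d)) stop("range layers are on different grids")
  out <- Reduce(`+`, lapply(ranges, function(r) {
    m <- (r == 1L) * 1L
    m[is.na(m)] <- 0L
    m
  }))
  dim(out) <- d
  out
}

# normalize a target-set: ranges as list of integer cell-id vectors,
# targets as matching integer vector
check_targets <- function(ranges, targets) {
  stopifnot(is.list(ranges), length(ranges) == length(targets))
  targets <- as.integer(round(targets))
  if (any(targets < 1L)) stop("targets must be >= 1")
  sizes <- lengths(ranges)
  bad <- which(targets > sizes)
  if (length(bad))
    stop("targets exceed range sizes for: ",
         paste(if (is.null(names(ranges))) bad else names(ranges)[bad], collapse = ", "))
  targets
}

#' Exact irreplaceability by subset enumeration
#'
#' The irreplaceability of a cell is the number of cell combinations that
#' include it, meet every species' conservation target, and would fail some
#' target if the cell were removed, divided by the total number of
#' combinations meeting all targets. Combinations are taken over all subset
#' sizes of the available cells; cells already protected contribute their
#' species coverage (`|P intersect R_s|`) toward the targets but are not
#' enumerated.
#'
#' @param cells Integer ids of the available (unprotected) cells.
#' @param ranges List of per-species cell-id vectors.
#' @param targets Per-species integer targets.
#' @param protected Integer ids of protected cells (locked contribution).
#' @param exact_limit Refuse instances with more than this many available
#'   cells (default 20; ~1e6 subsets).
#' @return Named numeric vector of irreplaceability values in `[0, 1]`, one
#'   per available cell (names are cell ids).
#' @export
irreplaceability_exact <- function(cells, ranges, targets, protected = integer(0),
                                   exact_limit = 20L) {
  targets <- check_targets(ranges, targets)
  cells <- as.integer(cells)
  n <- length(cells)
  if (n > exact_limit)
    stop("instance has ", n, " cells > exact_limit (", exact_limit,
         "); use irreplaceability_sampled")
  ns <- length(ranges)
  locked <- vapply(ranges, function(R) length(intersect(R, protected)), integer(1))
  t_eff <- pmax(targets - locked, 0L)
  # incidence over available cells
  B <- vapply(ranges, function(R) cells %in% R, logical(n))
  if (n == 1L) B <- matrix(B, nrow = 1L)
  avail <- colSums(B)
  infeasible <- which(avail < t_eff)
  if (length(infeasible))
    stop("targets infeasible for: ",
         paste(if (is.null(names(ranges))) infeasible else names(ranges)[infeasible],
               collapse = ", "))
  n_meet <- 0
  crit <- numeric(n)
  chunk <- 2^16
  total <- 2^n
  Bn <- matrix(as.numeric(B), n, ns)
  start <- 0
  bits <- 2^(seq_len(n) - 1L)
  while (start < total) {
    idx <- start + seq_len(min(chunk, total - start)) - 1
    S <- outer(idx, bits, function(i, b) (i %/% b) %% 2)  # subsets x cells
    counts <- S %*% Bn                                    # subsets x species
    t_mat <- matrix(t_eff, nrow(S), ns, byrow = TRUE)
    meets <- rowSums(counts >= t_mat) == ns
    n_meet <- n_meet + sum(meets)
    if (any(meets)) {
      tight <- (counts == t_mat) & (t_mat > 0L) & meets
      # cell x is removal-critical in subset C iff x in C and some species
      # containing x is exactly at its effective target
      anyc <- (tight %*% t(Bn)) > 0                       # subsets x cells
      crit <- crit + colSums(S * anyc * meets)
    }
    start <- start + chunk
  }
  if (n_meet == 0) stop("no subset meets the targets (infeasible instance)")
  stats::setNames(crit / n_meet, cells)
}

#' Sampled irreplaceability estimator
#'
#' Subsets are drawn by independent Bernoulli(`incl_prob`) inclusion of each
#' available cell; with the default 0.5 every subset is equiprobable, so
#' subsets that meet the targets are uniform over all meeting combinations
#' and the critical-count/meeting-count ratio is an unbiased binomial
#' estimate of the exact irreplaceability.
#'
#' @inheritParams irreplaceability_exact
#' @param n_samples Number of sampled subsets (>= 1000).
#' @param seed Integer seed; estimates are deterministic per seed.
#' @param incl_prob Per-cell inclusion probability (keep 0.5 for the
#'   definitional all-subset-sizes convention).
#' @return List: `estimate` and `se` (named per cell), `n_meeting` subsets.
#' @export
irreplaceability_sampled <- function(cells, ranges, targets, protected = integer(0),
                                     n_samples = 10000L, seed = 1L, incl_prob = 0.5) {
  if (n_samples < 1000L) stop("n_samples must be >= 1000")
  targets <- check_targets(ranges, targets)
  cells <- as.integer(cells)
  n <- length(cells)
  ns <- length(ranges)
  locked <- vapply(ranges, function(R) length(intersect(R, protected)), integer(1))
  t_eff <- pmax(targets - locked, 0L)
  B <- vapply(ranges, function(R) as.numeric(cells %in% R), numeric(n))
  if (n == 1L) B <- matrix(B, nrow = 1L)
  avail <- colSums(B)
  infeasible <- which(avail < t_eff)
  if (length(infeasible))
    stop("targets infeasible for: ",
         paste(if (is.null(names(ranges))) infeasible else names(ranges)[infeasible],
               collapse = ", "))
  n_meet <- 0
  crit <- numeric(n)
  inc <- numeric(n)  # meeting subsets containing each cell (diagnostic)
  with_seed(seed, {
    block <- max(1L, min(n_samples, floor(4e6 / max(n, 1L))))
    done <- 0L
    while (done < n_samples) {
      b <- min(block, n_samples - done)
      S <- matrix(stats::rbinom(b * n, 1L, incl_prob), b, n)
      counts <- S %*% B
      t_mat <- matrix(t_eff, b, ns, byrow = TRUE)
      meets <- rowSums(counts >= t_mat) == ns
      n_meet <- n_meet + sum(meets)
      if (any(meets)) {
        tight <- (counts == t_mat) & (t_mat > 0L) & meets
        anyc <- (tight %*% t(B)) > 0
        crit <- crit + colSums(S * anyc * meets)
        inc <- inc + colSums(S * meets)
      }
      done <- done + b
    }
  })
  if (n_meet == 0)
    stop("no sampled subset met the targets; increase n_samples or check feasibility")
  est <- crit / n_meet
  se <- sqrt(pmax(est * (1 - est), 0) / n_meet)
  se <- pmax(se, 1 / (2 * n_meet))  # keep 3-SE checks meaningful at 0/1
  list(estimate = stats::setNames(est, cells),
       se = stats::setNames(se, cells),
       n_meeting = n_meet)
}

# shared driver: irreplaceability over an arbitrary available-cell set,
# exact when small enough, sampled otherwise
irreplaceability_auto <- function(cells, ranges, targets, protected,
                                  exact_limit, n_samples, seed) {
  if (length(cells) <= exact_limit)
    irreplaceability_exact(cells, ranges, targets, protected, exact_limit)
  else
    irreplaceability_sampled(cells, ranges, targets, protected,
                             n_samples = n_samples, seed = seed)$estimate
}

#' Conservation-value layer (irreplaceability, no reserves)
#'
#' Irreplaceability of every range-bearing cell computed as if no cell were
#' protected: the "landscape" of conservation value. Cells outside all ranges
#' score 0.
#'
#' @param ranges List of binary range matrices on a shared grid.
#' @param targets Per-species integer targets (same order).
#' @param exact_limit Switch point between exact enumeration and sampling.
#' @param n_samples,seed Passed to the sampled estimator when needed.
#' @return Numeric matrix in `[0, 1]`.
#' @export
conservation_value <- function(ranges, targets, exact_limit = 20L,
                               n_samples = 10000L, seed = 1L) {
  rich <- richness(ranges)
  cells <- layer_which(rich, rich > 0L)
  out <- matrix(0, nrow(rich), ncol(rich))
  if (!length(cells)) return(out)
  sets <- lapply(ranges, function(r) layer_which(r, !is.na(r) & r == 1L))
  vals <- irreplaceability_auto(cells, sets, targets, integer(0),
                                exact_limit, n_samples, seed)
  `layer_values<-`(out, as.integer(names(vals)), as.numeric(vals))
}

#' Complementarity layer (irreplaceability given reserves)
#'
#' Irreplaceability of the unprotected range-bearing cells, crediting each
#' species' protected cells toward its target. Protected cells are masked
#' (`NA`) in the output; species already satisfied by reserves contribute
#' nothing.
#'
#' @inheritParams conservation_value
#' @param protected_cells Integer ids of protected cells.
#' @return Numeric matrix in `[0, 1]` with `NA` on protected cells.
#' @export
complementarity <- function(ranges, targets, protected_cells, exact_limit = 20L,
                            n_samples = 10000L, seed = 1L) {
  rich <- richness(ranges)
  cells <- setdiff(layer_which(rich, rich > 0L), protected_cells)
  out <- matrix(0, nrow(rich), ncol(rich))
  if (length(cells)) {
    sets <- lapply(ranges, function(r) layer_which(r, !is.na(r) & r == 1L))
    vals <- irreplaceability_auto(cells, sets, targets, as.integer(protected_cells),
                                  exact_limit, n_samples, seed)
    out <- `layer_values<-`(out, as.integer(names(vals)), as.numeric(vals))
  }
  if (length(protected_cells))
    out <- `layer_values<-`(out, as.integer(protected_cells), NA_real_)
  out
}
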