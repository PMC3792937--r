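# shared fixtures, built in code at test time

tiny_spec <- function(n = 20L, s = 1) grid_spec(0, 20, s, n, n)

small_world <- function(seed = 1, n = 48L, k = 4L, n_species = 4L,
                        records = c(1L, 15L, 20L, 25L), fraction = 0.1) {
  make_world(seed, grid_spec(10, 0, 0.25, n, n), k = k, n_species = n_species,
             n_predictors = 4L, records_per_species = records,
             reserve_fraction = fraction)
}

# random small irreplaceability instance: <= max_cells cells, <= max_species
# species, feasible targets
random_instance <- function(seed, max_cells = 12L, max_species = 4L) {
  set.seed(seed)
  n <- sample(4:max_cells, 1)
  ns <- sample(2:max_species, 1)
  cells <- sort(sample(1:100, n))
  ranges <- lapply(seq_len(ns), function(s) {
    sz <- sample(2:n, 1)
    sort(sample(cells, sz))
  })
  targets <- vapply(ranges, function(R) sample(seq_len(length(R)), 1), integer(1))
  list(cells = cells, ranges = ranges, targets = targets)
}

# all permutations of 1:n (tiny n only)
combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  sub <- combinat_perms(n - 1L)
  out <- list()
  for (p in sub) for (i in 0:(n - 1L))
    out[[length(out) + 1L]] <- append(p, n, after = i)
  out
}

# brute-force richness recount, cell by cell, independent of richness()
richness_oracle <- function(ranges) {
  d <- dim(ranges[[1]])
  out <- matrix(0L, d[1], d[2])
  for (r in seq_len(d[1])) for (cc in seq_len(d[2]))
    out[r, cc] <- sum(vapply(ranges, function(m) m[r, cc] == 1L, logical(1)))
  out
}

# independent brute-force irreplaceability by explicit subset listing
irr_oracle <- function(cells, ranges, targets, protected = integer(0)) {
  n <- length(cells)
  locked <- vapply(ranges, function(R) length(intersect(R, protected)), integer(1))
  subsets <- lapply(0:(2^n - 1), function(m) cells[bitwAnd(m, 2^(0:(n - 1))) > 0])
  meets <- vapply(subsets, function(C)
    all(vapply(seq_along(ranges), function(s)
      length(intersect(C, ranges[[s]])) + locked[s] >= targets[s], logical(1))),
    logical(1))
  vapply(cells, function(x) {
    num <- sum(vapply(which(meets), function(i) {
      C <- subsets[[i]]
      if (!x %in% C) return(FALSE)
      Cm <- setdiff(C, x)
      !all(vapply(seq_along(ranges), function(s)
        length(intersect(Cm, ranges[[s]])) + locked[s] >= targets[s], logical(1)))
    }, logical(1)))
    num / sum(meets)
  }, numeric(1))
}
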