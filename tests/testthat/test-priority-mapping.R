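test_that("richness counts overlapping ranges and matches a per-cell recount", {
  set.seed(40)
  ranges <- lapply(1:5, function(i) matrix(rbinom(64, 1, 0.3), 8, 8))
  rich <- richness(ranges)
  expect_equal(rich, richness_oracle(ranges))
  # removing one species lowers richness by exactly its indicator
  for (i in c(1, 3, 5))
    expect_equal(richness(ranges[-i]), rich - ranges[[i]])
  expect_error(richness(list(matrix(0, 3, 3), matrix(0, 4, 4))), "different grids")
})

test_that("worked combinatorial cases hold exactly", {
  # cell holding the sole occurrence of a species with t = 1
  irr <- irreplaceability_exact(cells = c(7L, 9L),
                                ranges = list(A = c(7L, 9L), B = 9L),
                                targets = c(1L, 1L))
  expect_equal(unname(irr["9"]), 1.0)
  # 2 cells, one species in both, t = 1 -> 1/3 each
  irr2 <- irreplaceability_exact(c(1L, 2L), list(A = c(1L, 2L)), 1L)
  expect_equal(unname(irr2), c(1, 1) / 3)
  # 3 cells, A in {1,2} t=1, B in {3} t=1 -> 1/3, 1/3, 1
  irr3 <- irreplaceability_exact(1:3, list(A = 1:2, B = 3L), c(1L, 1L))
  expect_equal(unname(irr3), c(1/3, 1/3, 1))
  # same instance with cell 3 protected: lock satisfies B, cells 1,2 keep 1/3
  irr3p <- irreplaceability_exact(1:2, list(A = 1:2, B = 3L), c(1L, 1L),
                                  protected = 3L)
  expect_equal(unname(irr3p), c(1/3, 1/3))
})

test_that("exact irreplaceability agrees with an independent enumeration oracle", {
  for (seed in 1:8) {
    inst <- random_instance(seed, max_cells = 8L)
    got <- irreplaceability_exact(inst$cells, inst$ranges, inst$targets)
    want <- irr_oracle(inst$cells, inst$ranges, inst$targets)
    expect_equal(unname(got), want, tolerance = 1e-12)
  }
  # with a random protected lock
  for (seed in 9:12) {
    inst <- random_instance(seed, max_cells = 7L)
    prot <- sample(unlist(inst$ranges), 2)
    cells <- setdiff(inst$cells, prot)
    feasible <- all(vapply(seq_along(inst$ranges), function(s)
      length(intersect(inst$ranges[[s]], c(cells, prot))) >= inst$targets[s], logical(1)))
    if (!feasible || !length(cells)) next
    got <- irreplaceability_exact(cells, inst$ranges, inst$targets, protected = prot)
    want <- irr_oracle(cells, inst$ranges, inst$targets, protected = prot)
    expect_equal(unname(got), want, tolerance = 1e-12)
  }
})

test_that("irreplaceability errors and edge cases behave as specified", {
  expect_error(irreplaceability_exact(1:2, list(A = 1:2), 5L), "exceed")
  expect_error(irreplaceability_exact(1L, list(A = 2L), 1L), "infeasible")
  expect_error(irreplaceability_exact(1:25, list(A = 1:25), 1L), "exact_limit")
  expect_error(irreplaceability_sampled(1:3, list(A = 1:3), 1L, n_samples = 10),
               ">= 1000")
  # species present everywhere with t = |cells|: every cell irreplaceable
  irr <- irreplaceability_exact(1:6, list(A = 1:6), 6L)
  expect_equal(unname(irr), rep(1, 6))
  s <- irreplaceability_sampled(1:5, list(A = 1:5), 5L, n_samples = 4000, seed = 3)
  expect_equal(unname(s$estimate), rep(1, 5))
})

test_that("sampled estimator matches exact values within 3 SE and is symmetric", {
  # symmetry: species everywhere, t = 1 -> all cells equal by symmetry
  ex <- irreplaceability_exact(1:10, list(A = 1:10), 1L)
  expect_equal(unname(ex), rep(ex[[1]], 10))
  s <- irreplaceability_sampled(1:10, list(A = 1:10), 1L, n_samples = 6000, seed = 5)
  expect_true(all(abs(s$estimate - ex) <= 3 * s$se))
  # oracle equivalence across random instances (subset of the acceptance sweep)
  for (seed in 1:10) {
    inst <- random_instance(seed)
    ex <- irreplaceability_exact(inst$cells, inst$ranges, inst$targets)
    sm <- irreplaceability_sampled(inst$cells, inst$ranges, inst$targets,
                                   n_samples = 4000, seed = 100 + seed)
    expect_true(all(abs(sm$estimate - ex) <= 3 * sm$se))
  }
})

test_that("relabelling species or reordering cells never changes values", {
  inst <- random_instance(31, max_cells = 9L)
  base <- irreplaceability_exact(inst$cells, inst$ranges, inst$targets)
  perm <- sample(length(inst$ranges))
  relab <- irreplaceability_exact(inst$cells, inst$ranges[perm], inst$targets[perm])
  expect_equal(base, relab)
  ord <- sample(length(inst$cells))
  reord <- irreplaceability_exact(inst$cells[ord], inst$ranges, inst$targets)
  expect_equal(base[as.character(inst$cells)], reord[as.character(inst$cells)])
})

test_that("conservation_value and complementarity layers honour their contracts", {
  # two species on a 4x4 grid
  r1 <- matrix(0L, 4, 4); r1[1, 1:2] <- 1L              # cells 1, 2
  r2 <- matrix(0L, 4, 4); r2[2, 2] <- 1L                # cell 6
  cons <- conservation_value(list(A = r1, B = r2), c(1L, 1L))
  expect_equal(cons[1, 1], 1/3)
  expect_equal(cons[1, 2], 1/3)
  expect_equal(cons[2, 2], 1)
  expect_equal(cons[3, 3], 0)                           # outside all ranges
  # equals the exact enumeration with an empty lock
  ex <- irreplaceability_exact(c(1L, 2L, 6L), list(A = c(1L, 2L), B = 6L), c(1L, 1L))
  expect_equal(c(cons[1, 1], cons[1, 2], cons[2, 2]), unname(ex))
  # complementarity with no reserves reduces to conservation value
  comp0 <- complementarity(list(A = r1, B = r2), c(1L, 1L), integer(0))
  expect_equal(comp0, cons)
  # a species fully satisfied by reserves contributes nothing
  comp <- complementarity(list(A = r1, B = r2), c(1L, 1L), protected_cells = 6L)
  expect_equal(comp[1, 1], 1/3)
  expect_equal(comp[1, 2], 1/3)
  expect_true(is.na(comp[2, 2]))                        # protected cells masked
  # cells holding only the satisfied species score 0
  r3 <- matrix(0L, 4, 4); r3[2, 2] <- 1L; r3[3, 3] <- 1L
  comp2 <- complementarity(list(B = r3), 1L, protected_cells = 6L)
  expect_equal(comp2[3, 3], 0)
})
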