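test_that("near-zero noise, one group, constant mean reproduces the mean in every cell", {
  sp <- sim_spec(n_areas = 20, group_props = 1,
                 traj_coeffs = array(15, dim = c(1, 2, 1)),
                 noise_sd = c(1e-12, 1e-12),
                 availability = matrix(TRUE, 2, 4), seed = 5)
  sim <- simulate_panel(sp)
  expect_equal(as.numeric(sim$panel$values), rep(15, 20 * 4 * 2),
               tolerance = 1e-9)
  expect_equal(sim$n_clipped, 0)
})

test_that("empirical group shares match mixing proportions at n = 10000", {
  tc <- array(rep(c(10, 40, 70), 4), dim = c(3, 2, 2))
  sp <- sim_spec(n_areas = 10000, group_props = c(0.2, 0.3, 0.5),
                 traj_coeffs = tc, noise_sd = c(1, 1),
                 availability = matrix(TRUE, 2, 4), seed = 42)
  sim <- simulate_panel(sp)
  shares <- tabulate(sim$true_labels, 3) / 10000
  expect_true(all(abs(shares - c(0.2, 0.3, 0.5)) < 0.015))
})

test_that("panel simulation is seed-deterministic and noise moments are honest", {
  sp <- three_group_spec(n_areas = 400, seed = 9)
  a <- simulate_panel(sp)
  b <- simulate_panel(sp)
  expect_identical(a$panel$values, b$panel$values)
  expect_identical(a$true_labels, b$true_labels)
  # per-cell noise SD within 3/sqrt(n) of the generating value (sd = 1)
  g1 <- a$true_labels == 1
  mu_11_t1 <- sum(sp$traj_coeffs[1, 1, ] * 1^(0:1))
  res <- a$panel$values[g1, 2, 1] - mu_11_t1
  n <- sum(g1)
  expect_lt(abs(sd(res) - 1), 3 / sqrt(n) + 0.05)
})

test_that("the default spec reproduces the census availability pattern", {
  sp <- sim_spec(n_areas = 10)
  av <- sp$availability
  expect_equal(dim(av), c(6, 4))
  expect_true(all(av[1:2, ]))           # in-mover shares at all censuses
  expect_false(any(av[3:6, 1]))         # age/tenure absent at the first
  expect_true(all(av[3:6, 2:4]))
  sim <- simulate_panel(sp)
  expect_true(all(is.na(sim$panel$values[, 1, 3:6])))
  expect_true(all(!is.na(sim$panel$values[, , 1:2])))
})

test_that("simulation spec rejects invalid inputs", {
  expect_error(sim_spec(n_areas = 10, group_props = c(0.5, 0.4)), "sum")
  expect_error(sim_spec(n_areas = 10, group_props = 1,
                        traj_coeffs = array(NaN, dim = c(1, 1, 1)),
                        noise_sd = 1, availability = matrix(TRUE, 1, 4)),
               "finite")
  expect_error(sim_spec(n_areas = 10, group_props = 1,
                        traj_coeffs = array(1, dim = c(1, 1, 1)),
                        noise_sd = -1, availability = matrix(TRUE, 1, 4)),
               "noise_sd")
  expect_error(sim_spec(n_areas = 10, group_props = 1,
                        traj_coeffs = array(1, dim = c(1, 1, 1)),
                        noise_sd = 1,
                        availability = matrix(FALSE, 1, 4)),
               "observable")
})

test_that("synthetic lookups are well-formed, deterministic, and cover both regimes", {
  one <- simulate_area_lookup(1, 1, seed = 3)
  expect_equal(nrow(one), 1)
  expect_equal(one$weight, 1)

  lk <- simulate_area_lookup(5, 3, seed = 11)
  sums <- tapply(lk$weight, lk$source_id, sum)
  expect_true(all(abs(sums - 1) < 1e-12))

  a <- simulate_area_lookup(100, 80, seed = 7)
  b <- simulate_area_lookup(100, 80, seed = 7)
  expect_identical(a, b)

  free <- simulate_area_lookup(10, 5, seed = 2, weighted = FALSE)
  expect_true(all(is.na(free$weight)))
})

test_that("paired classifications span independence to perfect association", {
  null_pair <- simulate_paired_classifications(100000, 4, 4, 0, seed = 1)
  v0 <- classification_association(null_pair$labels_a,
                                   null_pair$labels_b)$cramers_v
  expect_lt(v0, 0.02)

  perfect <- simulate_paired_classifications(5000, 3, 3, 1, seed = 2)
  v1 <- classification_association(perfect$labels_a,
                                   perfect$labels_b)$cramers_v
  expect_equal(v1, 1, tolerance = 1e-9)

  a <- simulate_paired_classifications(1000, 3, 5, 0.4, seed = 9)
  b <- simulate_paired_classifications(1000, 3, 5, 0.4, seed = 9)
  expect_identical(a, b)

  expect_error(simulate_paired_classifications(10, 2, 2, 1.2), "\\[0, 1\\]")
  expect_error(simulate_paired_classifications(10, 1, 2, 0.5), ">= 2")
})
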