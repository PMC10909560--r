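test_that("information criteria follow the trajectory-modelling convention", {
  expect_equal(bic_mixture(-100, 3, 100), -100 - 1.5 * log(100),
               tolerance = 1e-10)
  expect_equal(bic_mixture(-50, 0, 10), -50)
  expect_equal(aic_mixture(-100, 3), -103)
  expect_equal(aic_mixture(0, 0), 0)
  # penalty strictly increases with parameter count; AIC >= BIC when ln n > 2
  set.seed(1)
  for (i in 1:20) {
    ll <- runif(1, -1e5, 0); n <- sample(10:5000, 1)
    p1 <- sample(1:50, 1); p2 <- p1 + sample(1:10, 1)
    expect_lt(bic_mixture(ll, p2, n), bic_mixture(ll, p1, n))
    if (log(n) > 2)
      expect_gte(aic_mixture(ll, p1), bic_mixture(ll, p1, n))
  }
})

test_that("normalised entropy spans crisp to uninformative posteriors", {
  one_hot <- diag(3)[c(1, 2, 3, 1), ]
  expect_equal(class_entropy(one_hot), 1)
  expect_equal(class_entropy(matrix(1 / 4, 6, 4)), 0)
  hand <- rbind(c(0.9, 0.1), c(0.5, 0.5))
  expect_equal(class_entropy(hand),
               1 - (0.3251 + 0.6931) / (2 * 0.6931), tolerance = 5e-4)
  expect_equal(class_entropy(matrix(1, 5, 1)), 1)   # G = 1 convention
  # bounds on fuzzed posterior matrices
  for (seed in 1:20) {
    set.seed(seed)
    m <- matrix(rexp(8 * 3), 8, 3); m <- m / rowSums(m)
    e <- class_entropy(m)
    expect_gte(e, 0); expect_lte(e, 1)
  }
})

test_that("APPA is the mean assigned posterior, matching a brute-force group-by", {
  oh <- diag(2)[c(1, 1, 2), ]
  expect_equal(appa(oh), c(1, 1))
  p <- rbind(c(0.9, 0.1), c(0.7, 0.3), c(0.2, 0.8))
  expect_equal(appa(p), c(0.8, 0.8))
  for (seed in 1:15) {
    set.seed(seed)
    m <- matrix(rexp(20 * 3), 20, 3); m <- m / rowSums(m)
    lab <- max.col(m, ties.method = "first")
    brute <- sapply(1:3, function(j)
      if (any(lab == j)) mean(m[lab == j, j]) else NaN)
    expect_equal(suppressWarnings(appa(m, lab)), brute, tolerance = 1e-12)
  }
})

test_that("odds of correct classification and its inverse agree with worked values", {
  expect_equal(as.numeric(occ(0.5, 0.5)), 1)
  expect_equal(as.numeric(occ(0.9, 0.1)), 81, tolerance = 1e-10)
  expect_equal(as.numeric(occ(0.9845982, 0.63199)), 37.23, tolerance = 1e-3)
  capped <- occ(1, 0.3)
  expect_equal(as.numeric(capped), 9.5e7)
  expect_true(attr(capped, "capped"))

  expect_equal(invert_occ(0.9845982, 37.22547), 0.632, tolerance = 1e-3)
  expect_equal(round(100 * invert_occ(0.9999979, 95000000), 2), 0.50)
  expect_equal(invert_occ(0.5, 1), 0.5)
  # invert_occ after occ is the identity on its domain
  set.seed(2)
  for (i in 1:25) {
    a <- runif(1, 0.05, 0.999); p <- runif(1, 0.01, 0.99)
    expect_equal(invert_occ(a, as.numeric(occ(a, p))), p,
                 tolerance = 1e-9)
  }
})

test_that("mismatch compares assigned shares to estimated proportions and sums to zero", {
  oh <- diag(2)[c(1, 2, 2, 2), ]
  lab <- max.col(oh)
  expect_equal(mismatch(lab, colMeans(oh)), c(0, 0))
  expect_equal(mismatch(c(1, 1, 2, 2), c(0.49, 0.51)), c(0.01, -0.01))
  for (seed in 1:15) {
    set.seed(seed)
    m <- matrix(rexp(30 * 4), 30, 4); m <- m / rowSums(m)
    expect_lt(abs(sum(mismatch(max.col(m, ties.method = "first"),
                               colMeans(m)))), 1e-12)
  }
})

test_that("published six-group diagnostics invert to the published cluster shares", {
  appa_pub <- c(0.9845982, 0.9643457, 0.9475669, 0.9778698, 0.9862717,
                0.9999979)
  occ_pub <- c(37.22547, 100.0744, 150.0891, 2300.956, 2932.045, 95000000)
  shares <- round(100 * invert_occ(appa_pub, occ_pub), 1)
  expect_setequal(shares, c(63.2, 21.3, 10.7, 1.9, 2.4, 0.5))
})

test_that("fit_diagnostics is self-consistent with the model's own posteriors", {
  sp <- three_group_spec(n_areas = 300, seed = 13)
  fit <- gbmt(simulate_panel(sp)$panel, groups = 3, orders = 1, seed = 1,
              n_starts = 1)
  d <- fit_diagnostics(fit)
  expect_equal(as.numeric(d$occ),
               as.numeric(occ(appa(fit$posterior, fit$labels), fit$pi)))
  expect_equal(sum(d$mismatch), 0, tolerance = 1e-12)
  expect_gte(d$entropy, 0); expect_lte(d$entropy, 1)
  expect_equal(d$smallest_group_pct, 100 * min(fit$pi))
  expect_lt(d$bic_obs, d$aic)    # ln(n) > 2 here
})
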