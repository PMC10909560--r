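test_that("a single standard-normal cell at its mean gives log density -0.5 log(2 pi)", {
  v <- array(50, dim = c(1, 1, 1))
  p <- indicator_panel(v)
  ll <- gbmt_loglik(p, pi = 1, beta = list(list(50)), sigma = 1)
  expect_equal(ll, -0.5 * log(2 * pi), tolerance = 1e-12)
})

test_that("mixture log-likelihood and posteriors match the brute-force oracle", {
  for (seed in 1:60) {
    inst <- random_instance(seed)
    ll <- gbmt_loglik(inst$panel, inst$pi, inst$beta, inst$sigma)
    expect_equal(ll, bf_loglik(inst$panel$values, inst$pi, inst$beta,
                               inst$sigma), tolerance = 1e-10)
    post <- gbmt_posterior(inst$panel, inst$pi, inst$beta, inst$sigma)
    expect_equal(post, bf_posterior(inst$panel$values, inst$pi, inst$beta,
                                    inst$sigma), tolerance = 1e-10)
    expect_equal(rowSums(post), rep(1, nrow(post)), tolerance = 1e-12)
  }
})

test_that("a fully missing indicator contributes nothing to the likelihood", {
  inst <- random_instance(7)
  ll0 <- gbmt_loglik(inst$panel, inst$pi, inst$beta, inst$sigma)
  d <- dim(inst$panel$values)
  v2 <- array(NA_real_, dim = d + c(0, 0, 1))
  v2[, , seq_len(d[3])] <- inst$panel$values
  beta2 <- lapply(inst$beta, function(bg) c(bg, list(50)))
  ll1 <- gbmt_loglik(indicator_panel(v2), inst$pi, beta2,
                     c(inst$sigma, 1))
  expect_equal(ll1, ll0, tolerance = 1e-12)
})

test_that("posteriors respect symmetry and degenerate priors", {
  inst <- random_instance(3)
  G2 <- list(inst$beta[[1]], inst$beta[[1]])
  post <- gbmt_posterior(inst$panel, c(0.5, 0.5), G2, inst$sigma)
  expect_equal(post, matrix(0.5, nrow(post), 2), tolerance = 1e-12)
  post2 <- gbmt_posterior(inst$panel, c(1, 0), G2, inst$sigma)
  expect_equal(post2[, 1], rep(1, nrow(post2)))
})

test_that("likelihood is invariant to area order and to group relabelling", {
  inst <- random_instance(12)
  ll <- gbmt_loglik(inst$panel, inst$pi, inst$beta, inst$sigma)
  perm <- rev(seq_len(dim(inst$panel$values)[1]))
  ll_p <- gbmt_loglik(indicator_panel(inst$panel$values[perm, , ,
                                                        drop = FALSE]),
                      inst$pi, inst$beta, inst$sigma)
  expect_equal(ll, ll_p, tolerance = 1e-12)
  g_perm <- rev(seq_along(inst$pi))
  ll_g <- gbmt_loglik(inst$panel, inst$pi[g_perm], inst$beta[g_perm],
                      inst$sigma)
  expect_equal(ll, ll_g, tolerance = 1e-12)
})

test_that("zero-noise one-group panels are interpolated exactly", {
  tc <- array(0, dim = c(1, 1, 2)); tc[1, 1, ] <- c(20, 5)
  sp <- sim_spec(n_areas = 30, group_props = 1, traj_coeffs = tc,
                 noise_sd = 1e-12, availability = matrix(TRUE, 1, 4),
                 seed = 2)
  expect_warning(
    fit <- gbmt(simulate_panel(sp)$panel, groups = 1, orders = 1, seed = 1,
                n_starts = 1),
    "degenerate")
  expect_equal(fit$beta[[1]][[1]], c(20, 5), tolerance = 1e-6)
  expect_lte(fit$sigma[1], 1.1e-3)   # pinned at the scale floor
})

test_that("with one group the fit reduces to per-indicator weighted least squares", {
  sp <- three_group_spec(n_areas = 80, seed = 4)
  panel <- simulate_panel(sp)$panel
  fit <- gbmt(panel, groups = 1, orders = 1, seed = 1, n_starts = 1)
  time <- seq_along(panel$years) - 1
  for (k in 1:6) {
    yk <- panel$values[, , k]
    df <- data.frame(y = as.numeric(yk), t = rep(time, each = nrow(yk)))
    ols <- coef(lm(y ~ t, data = df))
    expect_equal(unname(fit$beta[[1]][[k]]), unname(ols), tolerance = 1e-6)
  }
})

test_that("EM recovers well-separated groups and their proportions", {
  sp <- three_group_spec(n_areas = 600, seed = 21)
  sim <- simulate_panel(sp)
  fit <- gbmt(sim$panel, groups = 3, orders = 1, seed = 2, n_starts = 2)
  expect_true(fit$converged)
  expect_gte(mclust::adjustedRandIndex(fit$labels, sim$true_labels), 0.95)
  expect_lt(max(abs(sort(fit$pi) - sort(sp$group_props))), 0.05)
  # trajectory means track the posterior-weighted empirical means
  for (k in c(1, 3)) {
    tm <- trajectory_means(fit, 1, k)
    in1 <- fit$labels == 1
    emp <- colMeans(sim$panel$values[in1, , k], na.rm = TRUE)
    expect_true(all(abs(tm - emp) < 0.5, na.rm = TRUE))
  }
})

test_that("the EM log-likelihood trace is non-decreasing on fuzzed panels", {
  for (seed in 1:6) {
    set.seed(seed)
    tc <- array(runif(2 * 2 * 2, 20, 80), dim = c(2, 2, 2))
    tc[, , 2] <- runif(4, -3, 3)
    sp <- sim_spec(n_areas = 120, group_props = c(0.4, 0.6),
                   traj_coeffs = tc, noise_sd = runif(2, 1, 6),
                   availability = matrix(TRUE, 2, 4), seed = seed)
    fit <- gbmt(simulate_panel(sp)$panel, groups = 2, orders = 1,
                seed = seed, n_starts = 1)
    expect_true(all(diff(fit$logL_trace) >= -1e-7 * abs(fit$logL)))
  }
})

test_that("trajectory means evaluate the polynomial at coded times", {
  sp <- three_group_spec(n_areas = 50, seed = 1)
  fit <- gbmt(simulate_panel(sp)$panel, groups = 1, orders = 1, seed = 1,
              n_starts = 1)
  fit$beta[[1]][[1]] <- 7            # order-0 constant
  expect_equal(unname(trajectory_means(fit, 1, 1)), rep(7, 4))
  fit$beta[[1]][[2]] <- c(2, 3)      # a + b t over t = 0..3
  expect_equal(unname(trajectory_means(fit, 1, 2)), c(2, 5, 8, 11))
})

test_that("model methods are coherent (predict, fitted, residuals, simulate, coef)", {
  sp <- three_group_spec(n_areas = 150, seed = 8)
  sim <- simulate_panel(sp)
  fit <- gbmt(sim$panel, groups = 3, orders = 1, seed = 3, n_starts = 1)
  expect_equal(predict(fit), fit$posterior)
  expect_equal(predict(fit, newdata = sim$panel), fit$posterior,
               tolerance = 1e-9)
  expect_equal(predict(fit, type = "class"), fit$labels)
  r <- residuals(fit)
  expect_equal(dim(r), dim(sim$panel$values))
  expect_lt(abs(mean(r, na.rm = TRUE)), 0.2)
  newp <- simulate(fit, nsim = 1, seed = 5)[[1]]
  expect_s3_class(newp$panel, "indicator_panel")
  expect_identical(is.na(newp$panel$values), is.na(sim$panel$values))
  cf <- coef(fit)
  expect_equal(dim(cf), c(3, 6, 2))
  expect_equal(cf[1, 1, 1:2], fit$beta[[1]][[1]],
               ignore_attr = TRUE)
})

test_that("invalid parameters and unidentifiable designs are rejected", {
  inst <- random_instance(5)
  expect_error(gbmt_loglik(inst$panel, inst$pi, inst$beta,
                           rep(-1, length(inst$sigma))), "positive")
  v <- array(NA_real_, dim = c(10, 4, 1)); v[, 1:2, 1] <- 50
  expect_error(gbmt(indicator_panel(v), groups = 1, orders = 3), "order")
  expect_error(gbmt(inst$panel, groups = 0), ">= 1")
})

test_that("the censored-normal family upweights boundary piles and keeps EM monotone", {
  set.seed(31)
  N <- 120; Tn <- 4
  mu <- 3 - 1.5 * (0:3)                 # latent mean dips below zero
  lat <- matrix(rnorm(N * Tn, rep(mu, each = N), 2), N, Tn)
  v <- array(pmin(pmax(lat, 0), 100), dim = c(N, Tn, 1))
  panel <- indicator_panel(v)
  fit_g <- gbmt(panel, groups = 1, orders = 1, seed = 1, n_starts = 1)
  fit_c <- gbmt(panel, groups = 1, orders = 1, seed = 1, n_starts = 1,
                family = "censored")
  expect_true(all(diff(fit_c$logL_trace) >= -1e-6 * abs(fit_c$logL)))
  # censoring-aware slope estimate is nearer the generating slope
  expect_lt(abs(fit_c$beta[[1]][[1]][2] - (-1.5)),
            abs(fit_g$beta[[1]][[1]][2] - (-1.5)))
})
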