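#' Fit a group-based multi-trajectory mixture model
#'
#' Fits a finite mixture of `groups` latent clusters to an indicator panel.
#' Conditional on cluster `g`, indicator `k` of area `i` at coded time `t`
#' is Gaussian around a polynomial mean
#' `mu_gk(t) = beta_gk0 + beta_gk1 t + ...`, independent across indicators
#' and times; the marginal likelihood of an area mixes the cluster-specific
#' likelihoods with proportions `pi_g`. Missing cells (the availability gaps
#' of early censuses, or undefined shares) simply drop out of the
#' likelihood (missing-at-random). Estimation is by expectation-maximisation:
#' the E-step computes posterior membership probabilities in log space, the
#' M-step updates `pi` as mean posteriors, each `beta_gk` by
#' posterior-weighted least squares on the time polynomial, and the noise
#' scales from posterior-weighted residuals. Multiple starts (k-means on
#' missing-aware time-averaged indicators, then jittered restarts) guard
#' against local optima; the best log-likelihood wins. Groups are
#' canonicalised by descending `pi` and ties in modal assignment break to
#' the lowest group index.
#'
#' An optional censored-normal family treats values at the 0/100 bounds as
#' censored observations of a latent Gaussian; its M-step maximises the
#' expected complete-data log-likelihood numerically per indicator.
#'
#' @param panel an [indicator_panel()].
#' @param groups number of latent groups `G >= 1`.
#' @param orders polynomial orders for the mean trajectories: a scalar, a
#'   length-`K` vector, or a `G x K` matrix; each order must lie in
#'   `0..T-1`. Default `T-1` (saturated in time).
#' @param variance `"shared"` (one noise SD per indicator, shared across
#'   groups — the default) or `"group"` (one per group and indicator).
#' @param family `"gaussian"` (default) or `"censored"` (normal censored at
#'   0 and 100).
#' @param max_iter maximum EM iterations per start.
#' @param tol relative log-likelihood convergence tolerance.
#' @param n_starts number of initialisations.
#' @param seed integer seed governing all starts.
#'
#' @return An object of class `gbmt`: a list with elements `pi`, `beta`
#'   (list of `G` lists of `K` coefficient vectors), `orders`, `sigma`
#'   (length-`K` vector or `G x K` matrix), `posterior` (`N x G`), `labels`,
#'   `logL`, `logL_trace`, `n_params`, `n_obs`, `converged`, `n_iter`,
#'   `family`, `variance`, and the fitting `panel`.
#' @seealso [summary.gbmt()], [fit_diagnostics()], [gbmt_enumerate()],
#'   [adjust_orders()], [trajectory_means()]
#' @examples
#' sp <- sim_spec(n_areas = 200, group_props = c(0.5, 0.5),
#'                traj_coeffs = array(c(10, 60, 2, -2), dim = c(2, 1, 2)),
#'                noise_sd = 2, availability = matrix(TRUE, 1, 4), seed = 1)
#' fit <- gbmt(simulate_panel(sp)$panel, groups = 2, orders = 1, seed = 1)
#' fit$pi
#' @export
gbmt <- function(panel, groups, orders = NULL,
                 variance = c("shared", "group"),
                 family = c("gaussian", "censored"),
                 max_iter = 500L, tol = 1e-8, n_starts = 3L, seed = 1L) {
  panel <- as_indicator_panel(panel)
  variance <- match.arg(variance)
  family <- match.arg(family)
  d <- dim(panel$values)
  N <- d[1]; Tn <- d[2]; K <- d[3]; G <- as.integer(groups)
  if (G < 1) stop("'groups' must be >= 1", call. = FALSE)
  if (N < G) stop("need at least as many areas as groups", call. = FALSE)
  if (tol <= 0) stop("'tol' must be > 0", call. = FALSE)
  orders <- normalize_orders(orders, G, K, Tn)
  check_identifiable(panel, orders)

  Y <- panel_matrix(panel)            # N x (T*K), time fastest
  obs <- !is.na(Y)
  n_obs <- sum(obs)
  time <- panel_time(panel)

  seeds <- derive_seeds(seed, max(n_starts, 1L))
  best <- NULL
  for (s in seq_len(max(n_starts, 1L))) {
    init_post <- init_posterior(Y, obs, Tn, K, G, seeds[s],
                                jitter = s > 1L)
    run <- em_run(Y, obs, time, Tn, K, G, orders, variance, family,
                  init_post, max_iter, tol)
    if (is.null(best) ||
        (run$ok && !best$ok) ||
        (run$ok == best$ok && run$logL > best$logL))
      best <- run
  }
  if (!best$converged)
    warning("EM did not converge in any start; returning best run",
            call. = FALSE)
  if (!best$ok)
    warning("all starts ended with a collapsed group or degenerate scale",
            call. = FALSE)

  # canonical order: descending mixing proportion
  ord_g <- order(best$pi, decreasing = TRUE)
  pi <- best$pi[ord_g]
  beta <- best$beta[ord_g]
  sigma <- if (is.matrix(best$sigma)) best$sigma[ord_g, , drop = FALSE]
           else best$sigma
  posterior <- best$posterior[, ord_g, drop = FALSE]
  orders <- orders[ord_g, , drop = FALSE]
  labels <- max.col(posterior, ties.method = "first")

  n_params <- (G - 1L) + sum(orders + 1L) +
    if (variance == "shared") K else G * K
  structure(
    list(pi = pi, beta = beta, orders = orders, sigma = sigma,
         posterior = posterior, labels = labels,
         logL = best$logL, logL_trace = best$trace,
         n_params = n_params, n_obs = n_obs,
         converged = best$converged, n_iter = length(best$trace),
         family = family, variance = variance,
         groups = G, panel = panel, seed = as.integer(seed),
         call = match.call()),
    class = "gbmt")
}

normalize_orders <- function(orders, G, K, Tn) {
  if (is.null(orders)) orders <- Tn - 1L
  if (is.matrix(orders)) {
    if (!all(dim(orders) == c(G, K)))
      stop("'orders' matrix must be G x K", call. = FALSE)
  } else if (length(orders) == 1L) {
    orders <- matrix(orders, G, K)
  } else if (length(orders) == K) {
    orders <- matrix(orders, G, K, byrow = TRUE)
  } else stop("'orders' must be scalar, length K, or G x K", call. = FALSE)
  storage.mode(orders) <- "integer"
  if (any(orders < 0L) || any(orders > Tn - 1L))
    stop("polynomial orders must lie in 0..T-1", call. = FALSE)
  orders
}

check_identifiable <- function(panel, orders) {
  Tn <- length(panel$years)
  for (k in seq_len(dim(panel$values)[3])) {
    obs_t <- apply(!is.na(panel$values[, , k, drop = FALSE]), 2, any)
    need <- max(orders[, k]) + 1L
    if (sum(obs_t) < need)
      stop(sprintf(
        "indicator %d has %d observed time points but order %d needs %d",
        k, sum(obs_t), max(orders[, k]), need), call. = FALSE)
  }
}

# log density / censored log-mass of each cell; Y may contain NA
cell_loglik <- function(Y, mu, sd_cell, family) {
  if (family == "gaussian")
    return(stats::dnorm(Y, mu, sd_cell, log = TRUE))
  out <- stats::dnorm(Y, mu, sd_cell, log = TRUE)
  lo <- !is.na(Y) & Y <= 0
  hi <- !is.na(Y) & Y >= 100
  if (any(lo))
    out[lo] <- stats::pnorm(0, mu[lo], sd_cell[lo], log.p = TRUE)
  if (any(hi))
    out[hi] <- stats::pnorm(100, mu[hi], sd_cell[hi], log.p = TRUE,
                            lower.tail = FALSE)
  out
}

# per-area log-likelihood under each group: N x G matrix
component_loglik <- function(Y, obs, time, Tn, K, beta, sigma, family) {
  N <- nrow(Y); G <- length(beta)
  L <- matrix(0, N, G)
  for (g in seq_len(G)) {
    mu <- group_mean_vector(beta[[g]], time, Tn, K)
    sd_k <- if (is.matrix(sigma)) sigma[g, ] else sigma
    sd_cell <- rep(sd_k, each = Tn)
    D <- cell_loglik(Y,
                     matrix(mu, N, Tn * K, byrow = TRUE),
                     matrix(sd_cell, N, Tn * K, byrow = TRUE), family)
    D[!obs] <- 0
    L[, g] <- rowSums(D)
  }
  L
}

# mean vector of one group over all T*K cells (time fastest)
group_mean_vector <- function(beta_g, time, Tn, K) {
  mu <- numeric(Tn * K)
  for (k in seq_len(K)) {
    b <- beta_g[[k]]
    mu[(k - 1L) * Tn + seq_len(Tn)] <-
      poly_design(time, length(b) - 1L) %*% b
  }
  mu
}

#' Mixture log-likelihood of a parameter set on a panel
#'
#' Evaluates `sum_i log sum_g pi_g prod_cells f(y | mu_gk(t), sigma)` for
#' explicit parameter values, without fitting. Missing cells contribute
#' nothing.
#'
#' @param panel an [indicator_panel()].
#' @param pi mixing proportions (length `G`, summing to 1).
#' @param beta trajectory coefficients: list of `G` lists of `K` numeric
#'   vectors, or a `G x K x (order+1)` array.
#' @param sigma noise SDs: length-`K` vector or `G x K` matrix, all > 0.
#' @param family `"gaussian"` or `"censored"`.
#' @return The scalar log-likelihood.
#' @seealso [gbmt_posterior()]
#' @export
gbmt_loglik <- function(panel, pi, beta, sigma, family = "gaussian") {
  pr <- prepare_params(panel, pi, beta, sigma)
  L <- component_loglik(pr$Y, pr$obs, pr$time, pr$Tn, pr$K, pr$beta,
                        pr$sigma, family)
  sum(row_logsumexp(sweep(L, 2L, log(pr$pi), `+`)))
}

#' Posterior group-membership probabilities for explicit parameters
#'
#' Computes `p_ig` proportional to `pi_g` times the group-conditional
#' likelihood of area `i`, normalised per area; evaluated in log space so
#' extreme likelihood ratios cannot underflow to 0/0.
#'
#' @inheritParams gbmt_loglik
#' @return `N x G` matrix with rows summing to 1.
#' @export
gbmt_posterior <- function(panel, pi, beta, sigma, family = "gaussian") {
  pr <- prepare_params(panel, pi, beta, sigma)
  L <- component_loglik(pr$Y, pr$obs, pr$time, pr$Tn, pr$K, pr$beta,
                        pr$sigma, family)
  lp <- sweep(L, 2L, log(pr$pi), `+`)
  post <- exp(lp - row_logsumexp(lp))
  post / rowSums(post)
}

prepare_params <- function(panel, pi, beta, sigma) {
  panel <- as_indicator_panel(panel)
  d <- dim(panel$values)
  if (any(!is.finite(pi)) || any(pi < 0))
    stop("'pi' must be finite and nonnegative", call. = FALSE)
  pi <- pi / sum(pi)
  beta <- as_beta_list(beta, length(pi), d[3])
  if (any(!is.finite(unlist(beta))))
    stop("trajectory coefficients must be finite", call. = FALSE)
  if (any(sigma <= 0) || any(!is.finite(sigma)))
    stop("'sigma' must be positive and finite", call. = FALSE)
  list(Y = panel_matrix(panel), obs = !is.na(panel$values),
       time = panel_time(panel), Tn = d[2], K = d[3],
       pi = pi, beta = beta, sigma = sigma)
}

as_beta_list <- function(beta, G, K) {
  if (is.array(beta) && length(dim(beta)) == 3L) {
    stopifnot(dim(beta)[1] == G, dim(beta)[2] == K)
    beta <- lapply(seq_len(G), function(g)
      lapply(seq_len(K), function(k) as.numeric(beta[g, k, ])))
  }
  if (!is.list(beta) || length(beta) != G ||
      !all(vapply(beta, length, 1L) == K))
    stop("'beta' must be a G x K x (order+1) array or list of G lists of K",
         call. = FALSE)
  beta
}

# ---- initialisation ---------------------------------------------------

# missing-aware k-means start: per-area time means per indicator
init_posterior <- function(Y, obs, Tn, K, G, seed, jitter = FALSE) {
  N <- nrow(Y)
  if (G == 1L) return(matrix(1, N, 1L))
  feats <- matrix(0, N, K)
  for (k in seq_len(K)) {
    cols <- (k - 1L) * Tn + seq_len(Tn)
    m <- rowMeans(Y[, cols, drop = FALSE], na.rm = TRUE)
    m[is.nan(m)] <- NA
    m[is.na(m)] <- mean(m, na.rm = TRUE)
    feats[, k] <- m
  }
  feats[is.na(feats)] <- 0
  set.seed(as.integer(seed))
  if (jitter)
    feats <- feats + matrix(stats::rnorm(N * K, sd = apply(feats, 2, stats::sd) / 2 + 1e-8),
                            N, K, byrow = FALSE)
  km <- tryCatch(stats::kmeans(feats, centers = G, nstart = 5L,
                               iter.max = 50L),
                 error = function(e)
                   list(cluster = sample.int(G, N, replace = TRUE)))
  # relabel clusters by descending size so row g of a per-group 'orders'
  # matrix addresses the same (canonical) group across refits
  size_rank <- order(order(tabulate(km$cluster, G), decreasing = TRUE))
  cl <- size_rank[km$cluster]
  post <- matrix(0.1 / (G - 1), N, G)
  post[cbind(seq_len(N), cl)] <- 0.9
  post
}

# ---- EM ---------------------------------------------------------------

em_run <- function(Y, obs, time, Tn, K, G, orders, variance, family,
                   post, max_iter, tol) {
  sigma_floor <- 1e-3
  par <- m_step(Y, obs, time, Tn, K, G, orders, variance, family,
                post, sigma_floor, par = NULL)
  trace <- numeric(0)
  prev <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    L <- component_loglik(Y, obs, time, Tn, K, par$beta, par$sigma, family)
    lp <- sweep(L, 2L, log(pmax(par$pi, 1e-300)), `+`)
    lse <- row_logsumexp(lp)
    logL <- sum(lse)
    trace <- c(trace, logL)
    post <- exp(lp - lse)
    post <- post / rowSums(post)
    if (is.finite(prev) && abs(logL - prev) <= tol * (abs(prev) + 1e-3)) {
      converged <- TRUE
      break
    }
    prev <- logL
    par <- m_step(Y, obs, time, Tn, K, G, orders, variance, family,
                  post, sigma_floor, par)
  }
  ok <- all(par$pi >= 1e-4) && all(par$sigma > sigma_floor * 1.0001)
  list(pi = par$pi, beta = par$beta, sigma = par$sigma,
       posterior = post, logL = trace[length(trace)], trace = trace,
       converged = converged, ok = ok)
}

m_step <- function(Y, obs, time, Tn, K, G, orders, variance, family,
                   post, sigma_floor, par) {
  N <- nrow(Y)
  pi <- pmax(colMeans(post), 1e-12)
  pi <- pi / sum(pi)
  if (family == "censored")
    return(m_step_censored(Y, obs, time, Tn, K, G, orders, variance,
                           post, pi, sigma_floor, par))
  beta <- vector("list", G)
  rss <- matrix(0, G, K)
  wn <- matrix(0, G, K)
  for (g in seq_len(G)) {
    w <- post[, g]
    beta[[g]] <- vector("list", K)
    for (k in seq_len(K)) {
      cols <- (k - 1L) * Tn + seq_len(Tn)
      Yk <- Y[, cols, drop = FALSE]
      Ok <- obs[, cols, drop = FALSE]
      Y0 <- Yk; Y0[!Ok] <- 0
      s0 <- colSums(w * Ok)                 # per-time weight mass
      s1 <- colSums(w * Y0)
      X <- poly_design(time, orders[g, k])
      XtWX <- crossprod(X, s0 * X)
      XtWy <- crossprod(X, s1)
      b <- tryCatch(solve(XtWX, XtWy),
                    error = function(e)
                      solve(XtWX + diag(1e-8, ncol(X)), XtWy))
      b <- as.numeric(b)
      beta[[g]][[k]] <- b
      f <- as.numeric(X %*% b)
      E2 <- sweep(Yk, 2L, f)^2
      E2[!Ok] <- 0
      rss[g, k] <- sum(w * rowSums(E2))
      wn[g, k] <- sum(w * rowSums(Ok))
    }
  }
  sigma <- if (variance == "shared") {
    pmax(sqrt(colSums(rss) / pmax(colSums(wn), 1e-12)), sigma_floor)
  } else {
    pmax(sqrt(rss / pmax(wn, 1e-12)), sigma_floor)
  }
  list(pi = pi, beta = beta, sigma = sigma)
}

# numerical M-step for the censored-normal family: per indicator, maximise
# the posterior-weighted censored log-likelihood over all group coefficients
# and the noise scale(s) jointly
m_step_censored <- function(Y, obs, time, Tn, K, G, orders, variance,
                            post, pi, sigma_floor, par) {
  N <- nrow(Y)
  # fall back to a gaussian M-step for starting values
  gpar <- m_step(Y, obs, time, Tn, K, G, orders, variance, "gaussian",
                 post, sigma_floor, par = NULL)
  if (is.null(par)) par <- gpar
  beta <- par$beta
  sigma <- par$sigma
  for (k in seq_len(K)) {
    cols <- (k - 1L) * Tn + seq_len(Tn)
    Yk <- Y[, cols, drop = FALSE]
    Ok <- obs[, cols, drop = FALSE]
    Xg <- lapply(seq_len(G), function(g) poly_design(time, orders[g, k]))
    nb <- vapply(Xg, ncol, 1L)
    n_sig <- if (variance == "shared") 1L else G
    theta0 <- c(unlist(lapply(seq_len(G), function(g) beta[[g]][[k]])),
                log(if (variance == "shared") sigma[k] else sigma[, k]))
    negQ <- function(theta) {
      off <- 0L
      val <- 0
      sig <- pmax(exp(theta[length(theta) - n_sig + seq_len(n_sig)]),
                  sigma_floor)
      for (g in seq_len(G)) {
        b <- theta[off + seq_len(nb[g])]; off <- off + nb[g]
        mu_t <- as.numeric(Xg[[g]] %*% b)
        sg <- if (n_sig == 1L) sig else sig[g]
        D <- cell_loglik(Yk, matrix(mu_t, N, Tn, byrow = TRUE),
                         matrix(sg, N, Tn), "censored")
        D[!Ok] <- 0
        val <- val + sum(post[, g] * rowSums(D))
      }
      -val
    }
    opt <- stats::optim(theta0, negQ, method = "BFGS",
                        control = list(maxit = 200))
    theta <- if (opt$value <= negQ(theta0)) opt$par else theta0
    off <- 0L
    for (g in seq_len(G)) {
      beta[[g]][[k]] <- theta[off + seq_len(nb[g])]; off <- off + nb[g]
    }
    sig <- pmax(exp(theta[length(theta) - n_sig + seq_len(n_sig)]),
                sigma_floor)
    if (variance == "shared") sigma[k] <- sig else sigma[, k] <- sig
  }
  list(pi = pi, beta = beta, sigma = sigma)
}

#' Polynomial mean trajectory of one group and indicator
#'
#' Evaluates the fitted mean `mu_gk(t)` at the panel's coded time points —
#' the quantity drawn in trajectory plots.
#'
#' @param model a fitted [gbmt()] object.
#' @param group group index (after canonical descending-`pi` ordering).
#' @param indicator indicator index or name.
#' @return Numeric vector over the panel's time points, named by year.
#' @export
trajectory_means <- function(model, group, indicator) {
  stopifnot(inherits(model, "gbmt"))
  if (is.character(indicator))
    indicator <- match(indicator, model$panel$indicators)
  b <- model$beta[[group]][[indicator]]
  time <- panel_time(model$panel)
  out <- as.numeric(poly_design(time, length(b) - 1L) %*% b)
  names(out) <- model$panel$years
  out
}
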