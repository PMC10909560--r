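# Unvectorised reference implementations used as independent oracles for
# the mixture likelihood and posterior computations, plus generators for
# small random instances.

# beta: list of G lists of K coefficient vectors; values: N x T x K array
bf_component_loglik <- function(values, beta, sigma) {
  d <- dim(values)
  G <- length(beta)
  L <- matrix(0, d[1], G)
  for (i in seq_len(d[1])) {
    for (g in seq_len(G)) {
      ll <- 0
      for (k in seq_len(d[3])) {
        b <- beta[[g]][[k]]
        sd_k <- if (is.matrix(sigma)) sigma[g, k] else sigma[k]
        for (t in seq_len(d[2])) {
          y <- values[i, t, k]
          if (is.na(y)) next
          mu <- sum(b * (t - 1)^(seq_along(b) - 1))
          ll <- ll + dnorm(y, mu, sd_k, log = TRUE)
        }
      }
      L[i, g] <- ll
    }
  }
  L
}

bf_loglik <- function(values, pi, beta, sigma) {
  L <- bf_component_loglik(values, beta, sigma)
  tot <- 0
  for (i in seq_len(nrow(L))) {
    li <- log(pi) + L[i, ]
    m <- max(li)                        # guard against exp underflow
    tot <- tot + m + log(sum(exp(li - m)))
  }
  tot
}

bf_posterior <- function(values, pi, beta, sigma) {
  L <- bf_component_loglik(values, beta, sigma)
  post <- matrix(0, nrow(L), ncol(L))
  for (i in seq_len(nrow(L))) {
    li <- log(pi) + L[i, ]
    num <- exp(li - max(li))
    post[i, ] <- num / sum(num)
  }
  post
}

# random small mixture instance (bounded so exp() in the oracle is safe)
random_instance <- function(seed) {
  set.seed(seed)
  N <- sample(2:5, 1); G <- sample(1:3, 1)
  K <- sample(1:2, 1); Tn <- sample(2:3, 1)
  values <- array(runif(N * Tn * K, 20, 80), dim = c(N, Tn, K))
  # sprinkle missing cells but keep every indicator partly observed
  miss <- runif(N * Tn * K) < 0.2
  values[miss] <- NA
  for (k in seq_len(K))
    if (all(is.na(values[, , k]))) values[1, 1, k] <- 50
  pi <- as.numeric(rexp(G) + 0.1); pi <- pi / sum(pi)
  beta <- lapply(seq_len(G), function(g)
    lapply(seq_len(K), function(k) runif(sample(1:Tn, 1), 20, 80)))
  sigma <- runif(K, 2, 10)
  list(panel = indicator_panel(values), pi = pi, beta = beta, sigma = sigma)
}

# well-separated three-group study design: K = 6 indicators, 4 censuses,
# age/tenure indicators unavailable at the first census, unit noise so the
# stated mean gaps are gaps in noise SDs
three_group_spec <- function(n_areas = 2000, seed = 1) {
  tc <- array(0, dim = c(3, 6, 2))
  base <- rbind(c(10, 2, 20, 10, 30, 10),   # group means, gap >= 10 = 10 SD
                c(30, 12, 40, 25, 50, 30),
                c(50, 22, 60, 40, 70, 50))
  slope <- rbind(c(1, 0.5, -1, 0, 1, 0),
                 c(-1, 0, 1, 1, 0, -1),
                 c(0, 1, 0, -1, -1, 1))
  tc[, , 1] <- base
  tc[, , 2] <- slope
  avail <- matrix(TRUE, 6, 4); avail[3:6, 1] <- FALSE
  sim_spec(n_areas = n_areas, n_timepoints = 4,
           group_props = c(0.5, 0.3, 0.2), traj_coeffs = tc,
           noise_sd = rep(1, 6), availability = avail, seed = seed)
}
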