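#' Enumerate candidate models over a range of group counts
#'
#' Fits one model per candidate `G`, collects the diagnostic battery of
#' [fit_diagnostics()] into a table, and flags an advisory "elbow": the `G`
#' beyond which the absolute BIC improvement first falls below `elbow_frac`
#' times the preceding improvement (the "levelling out" of the
#' criterion curve). Class enumeration in practice combines these indices
#' with interpretability, so the elbow is a hint, never a decision.
#'
#' Failed fits are recorded per row and enumeration continues.
#'
#' @param panel an [indicator_panel()].
#' @param G_range integer vector of candidate group counts.
#' @param elbow_frac fraction of the preceding BIC gain under which the
#'   curve is declared to level out.
#' @param ... further arguments passed to [gbmt()] (orders, variance,
#'   n_starts, seed, ...).
#' @return A list of class `gbmt_enumeration`: `table` (one diagnostics row
#'   per `G`, plus `logL`, `n_params`, `converged`, `error`), `models`
#'   (named list of fits), `best_bic_obs` (G preferred by `bic_obs`),
#'   `elbow` (advisory G or `NA`).
#' @export
gbmt_enumerate <- function(panel, G_range, elbow_frac = 0.5, ...) {
  if (!length(G_range)) stop("'G_range' must be nonempty", call. = FALSE)
  G_range <- sort(unique(as.integer(G_range)))
  models <- vector("list", length(G_range))
  names(models) <- paste0("G", G_range)
  rows <- vector("list", length(G_range))
  for (i in seq_along(G_range)) {
    G <- G_range[i]
    fit <- tryCatch(gbmt(panel, groups = G, ...), error = identity)
    if (inherits(fit, "error")) {
      rows[[i]] <- data.frame(G = G, logL = NA, n_params = NA,
                              bic_obs = NA, bic_subjects = NA, aic = NA,
                              entropy = NA, smallest_group_pct = NA,
                              converged = FALSE,
                              error = conditionMessage(fit))
      next
    }
    models[[i]] <- fit
    d <- fit_diagnostics(fit)
    rows[[i]] <- data.frame(G = G, logL = fit$logL,
                            n_params = fit$n_params,
                            bic_obs = d$bic_obs,
                            bic_subjects = d$bic_subjects, aic = d$aic,
                            entropy = d$entropy,
                            smallest_group_pct = d$smallest_group_pct,
                            converged = fit$converged, error = NA_character_)
  }
  tab <- do.call(rbind, rows)
  ok <- !is.na(tab$bic_obs)
  best <- if (any(ok)) tab$G[ok][which.max(tab$bic_obs[ok])] else NA_integer_
  elbow <- NA_integer_
  if (sum(ok) >= 3) {
    b <- tab$bic_obs[ok]; Gs <- tab$G[ok]
    gain <- diff(b)
    for (j in 2:length(gain)) {
      if (is.finite(gain[j]) && is.finite(gain[j - 1]) &&
          abs(gain[j]) < elbow_frac * abs(gain[j - 1])) {
        elbow <- Gs[j]   # the G where the previous gain levelled out
        break
      }
    }
  }
  structure(list(table = tab, models = models, best_bic_obs = best,
                 elbow = elbow),
            class = "gbmt_enumeration")
}

#' @export
print.gbmt_enumeration <- function(x, ...) {
  cat("Model enumeration over G:\n")
  print(x$table[, c("G", "bic_obs", "aic", "entropy",
                    "smallest_group_pct", "converged")],
        row.names = FALSE)
  cat(sprintf("Preferred by BIC(obs): G = %s; advisory elbow: G = %s\n",
              x$best_bic_obs, x$elbow))
  invisible(x)
}

#' Backward adjustment of polynomial orders by Wald tests
#'
#' Starting from a fitted model, repeatedly drops the highest-order
#' trajectory coefficient of every (group, indicator) whose Wald statistic
#' (coefficient over its posterior-weighted least-squares standard error, a
#' pseudo-class approximation) is not significant at level `alpha`, then
#' refits, until every retained top-order term is significant or all orders
#' reach zero. The refitted model usually improves the information criteria
#' slightly; the post-adjustment BIC is reported but not enforced.
#'
#' @param model a [gbmt()] fit (typically at maximal orders).
#' @param alpha Wald significance level in (0, 1).
#' @param max_rounds cap on remove-and-refit rounds.
#' @return A refitted `gbmt` object with (possibly) reduced `orders`, plus
#'   attribute `adjustment_path` recording orders per round.
#' @export
adjust_orders <- function(model, alpha = 0.05, max_rounds = 10L) {
  stopifnot(inherits(model, "gbmt"))
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop("'alpha' must lie strictly in (0, 1)", call. = FALSE)
  panel <- model$panel
  path <- list(model$orders)
  fit <- model
  for (round in seq_len(max_rounds)) {
    p_top <- top_term_pvalues(fit)
    orders <- fit$orders      # in the fit's canonical group order
    drop <- !is.na(p_top) & p_top > alpha & orders > 0L
    if (!any(drop)) break
    orders[drop] <- orders[drop] - 1L
    fit <- gbmt(panel, groups = model$groups, orders = orders,
                variance = model$variance, family = model$family,
                n_starts = 1L, seed = model$seed)
    path <- c(path, list(orders))
  }
  attr(fit, "adjustment_path") <- path
  fit
}

# Wald p-value of the top-order coefficient per (group, indicator), from
# posterior-weighted least squares conditional on the current posteriors
top_term_pvalues <- function(model) {
  panel <- model$panel
  d <- dim(panel$values)
  Tn <- d[2]; K <- d[3]; G <- model$groups
  Y <- panel_matrix(panel)
  obs <- !is.na(Y)
  time <- panel_time(panel)
  out <- matrix(NA_real_, G, K)
  for (g in seq_len(G)) {
    w <- model$posterior[, g]
    for (k in seq_len(K)) {
      o <- model$orders[g, k]
      if (o == 0L) next
      cols <- (k - 1L) * Tn + seq_len(Tn)
      Yk <- Y[, cols, drop = FALSE]
      Ok <- obs[, cols, drop = FALSE]
      Y0 <- Yk; Y0[!Ok] <- 0
      s0 <- colSums(w * Ok)
      s1 <- colSums(w * Y0)
      X <- poly_design(time, o)
      XtWX <- crossprod(X, s0 * X)
      b <- tryCatch(solve(XtWX, crossprod(X, s1)),
                    error = function(e) NULL)
      if (is.null(b)) next
      f <- as.numeric(X %*% b)
      E2 <- sweep(Yk, 2L, f)^2
      E2[!Ok] <- 0
      wn <- sum(w * rowSums(Ok))
      df <- wn - (o + 1)
      if (df <= 1) next
      s2 <- sum(w * rowSums(E2)) / df
      V <- tryCatch(s2 * solve(XtWX), error = function(e) NULL)
      if (is.null(V)) next
      se <- sqrt(V[o + 1L, o + 1L])
      z <- b[o + 1L] / se
      out[g, k] <- 2 * stats::pt(-abs(z), df = df)
    }
  }
  out
}
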