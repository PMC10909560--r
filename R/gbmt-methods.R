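#' @export
print.gbmt <- function(x, ...) {
  cat(sprintf("Group-based multi-trajectory model: %d groups, %d areas\n",
              x$groups, nrow(x$posterior)))
  cat(sprintf("Family: %s, variance: %s, logL = %.2f (%d parameters, %d cells)\n",
              x$family, x$variance, x$logL, x$n_params, x$n_obs))
  cat("Mixing proportions:",
      paste(sprintf("%.3f", x$pi), collapse = " "), "\n")
  if (!x$converged) cat("Warning: EM did not converge\n")
  invisible(x)
}

#' Summarise a fitted multi-trajectory model
#'
#' Prints the enumeration diagnostics (information criteria, normalised
#' entropy, per-group APPA / OCC / mismatch, smallest group) together with
#' group sizes.
#'
#' @param object a [gbmt()] fit.
#' @param ... unused.
#' @return Invisibly, the [fit_diagnostics()] list.
#' @export
summary.gbmt <- function(object, ...) {
  d <- fit_diagnostics(object)
  print(object)
  cat(sprintf("BIC (obs n=%d): %.2f   BIC (areas n=%d): %.2f   AIC: %.2f\n",
              object$n_obs, d$bic_obs, nrow(object$posterior),
              d$bic_subjects, d$aic))
  cat(sprintf("Entropy: %.3f   Smallest group: %.2f%%\n",
              d$entropy, d$smallest_group_pct))
  tab <- data.frame(group = seq_len(object$groups),
                    pi = round(object$pi, 5),
                    assigned = as.integer(tabulate(object$labels,
                                                   object$groups)),
                    APPA = round(d$appa, 6),
                    OCC = signif(d$occ, 6),
                    mismatch = signif(d$mismatch, 4))
  print(tab, row.names = FALSE)
  invisible(d)
}

#' @export
coef.gbmt <- function(object, ...) {
  K <- length(object$panel$indicators)
  mx <- max(object$orders) + 1L
  out <- array(NA_real_, dim = c(object$groups, K, mx),
               dimnames = list(paste0("g", seq_len(object$groups)),
                               object$panel$indicators,
                               paste0("t^", 0:(mx - 1))))
  for (g in seq_len(object$groups)) for (k in seq_len(K)) {
    b <- object$beta[[g]][[k]]
    out[g, k, seq_along(b)] <- b
  }
  out
}

#' @export
logLik.gbmt <- function(object, ...) {
  structure(object$logL, df = object$n_params, nobs = object$n_obs,
            class = "logLik")
}

#' Posterior memberships for new areas
#'
#' Applies a fitted model's parameters to a new indicator panel (same years
#' and indicators) and returns posterior group-membership probabilities; with
#' `type = "class"` the modal labels.
#'
#' @param object a [gbmt()] fit.
#' @param newdata an [indicator_panel()]; default the fitting panel.
#' @param type `"posterior"` (default) or `"class"`.
#' @param ... unused.
#' @return `N x G` probability matrix, or integer labels.
#' @export
predict.gbmt <- function(object, newdata = NULL,
                         type = c("posterior", "class"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    post <- object$posterior
  } else {
    post <- gbmt_posterior(newdata, object$pi, object$beta, object$sigma,
                           family = object$family)
  }
  if (type == "class") max.col(post, ties.method = "first") else post
}

#' @export
fitted.gbmt <- function(object, ...) {
  panel <- object$panel
  d <- dim(panel$values)
  time <- panel_time(panel)
  out <- array(NA_real_, dim = d, dimnames = dimnames(panel$values))
  mu_g <- lapply(seq_len(object$groups), function(g)
    sapply(seq_len(d[3]), function(k) {
      b <- object$beta[[g]][[k]]
      as.numeric(poly_design(time, length(b) - 1L) %*% b)
    }))
  for (i in seq_len(d[1])) out[i, , ] <- mu_g[[object$labels[i]]]
  out
}

#' @export
residuals.gbmt <- function(object, ...) {
  object$panel$values - fitted(object)
}

#' Simulate panels from a fitted multi-trajectory model
#'
#' Draws `nsim` new panels: group labels from the fitted mixing proportions,
#' then Gaussian cells around the fitted trajectories, clipped to
#' \[0, 100\], with the fitting panel's missingness pattern applied.
#'
#' @param object a [gbmt()] fit.
#' @param nsim number of panels.
#' @param seed integer seed.
#' @param ... unused.
#' @return A list of `nsim` lists, each with `panel` and `labels`.
#' @export
simulate.gbmt <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  panel <- object$panel
  d <- dim(panel$values)
  time <- panel_time(panel)
  miss <- is.na(panel$values)
  lapply(seq_len(nsim), function(s) {
    labels <- sample.int(object$groups, d[1], replace = TRUE,
                         prob = object$pi)
    values <- array(NA_real_, dim = d, dimnames = dimnames(panel$values))
    for (i in seq_len(d[1])) {
      g <- labels[i]
      for (k in seq_len(d[3])) {
        b <- object$beta[[g]][[k]]
        mu <- as.numeric(poly_design(time, length(b) - 1L) %*% b)
        sdk <- if (is.matrix(object$sigma)) object$sigma[g, k]
               else object$sigma[k]
        values[i, , k] <- stats::rnorm(d[2], mu, sdk)
      }
    }
    values[values < 0] <- 0
    values[values > 100] <- 100
    values[miss] <- NA_real_
    list(panel = indicator_panel(values, areas = panel$areas,
                                 years = panel$years,
                                 indicators = panel$indicators),
         labels = labels)
  })
}

#' Plot fitted group trajectories
#'
#' One panel per indicator, mean trajectory lines per group over the census
#' years — the standard way to read a multi-trajectory solution.
#'
#' @param x a [gbmt()] fit.
#' @param indicators which indicators to draw (indices or names); default
#'   all.
#' @param ... passed to [graphics::matplot()].
#' @return Invisibly, `x`.
#' @export
plot.gbmt <- function(x, indicators = NULL, ...) {
  panel <- x$panel
  K <- length(panel$indicators)
  if (is.null(indicators)) indicators <- seq_len(K)
  if (is.character(indicators))
    indicators <- match(indicators, panel$indicators)
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(indicators)),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  cols <- grDevices::hcl.colors(x$groups, "Dark 3")
  for (k in indicators) {
    tm <- sapply(seq_len(x$groups), function(g) trajectory_means(x, g, k))
    graphics::matplot(panel$years, tm, type = "b", pch = 16, lty = 1,
                      col = cols, xlab = "Census year",
                      ylab = "%", main = panel$indicators[k], ...)
  }
  invisible(x)
}
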