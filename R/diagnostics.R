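#' Information criteria on the trajectory-modelling scale
#'
#' `bic_mixture()` returns `logL - 0.5 * n_params * log(n)` and
#' `aic_mixture()` returns `logL - n_params`: the sign convention used
#' throughout the group-based trajectory literature, where criteria are
#' reported as (large negative) numbers and *larger* (less negative) is
#' better. Two sample-size conventions are in circulation for panel
#' mixtures — the number of non-missing observation cells and the number of
#' areas; pass the one you mean as `n` (fitted models carry both via
#' [fit_diagnostics()]).
#'
#' @param logL maximised log-likelihood.
#' @param n_params number of free parameters.
#' @param n sample size (>= 1).
#' @return Numeric scalar.
#' @examples
#' bic_mixture(-100, 3, 100)  # -106.9078
#' @export
bic_mixture <- function(logL, n_params, n) {
  if (any(n < 1)) stop("'n' must be >= 1", call. = FALSE)
  logL - 0.5 * n_params * log(n)
}

#' @rdname bic_mixture
#' @export
aic_mixture <- function(logL, n_params) logL - n_params

#' Normalised entropy of a posterior-membership matrix
#'
#' `1 - (-sum p log p) / (N log G)`: 1 for perfectly crisp assignment,
#' 0 for uniformly uncertain rows. Defined as 1 when `G = 1`.
#'
#' @param posteriors `N x G` matrix with rows summing to 1.
#' @return Scalar in \[0, 1\].
#' @export
class_entropy <- function(posteriors) {
  posteriors <- as.matrix(posteriors)
  G <- ncol(posteriors)
  if (G == 1L) return(1)
  if (any(abs(rowSums(posteriors) - 1) > 1e-6))
    stop("posterior rows must sum to 1", call. = FALSE)
  plogp <- posteriors * log(posteriors)
  plogp[posteriors == 0] <- 0
  1 - (-sum(plogp)) / (nrow(posteriors) * log(G))
}

#' Average posterior probability of assignment per group
#'
#' `APPA_j` is the mean posterior probability of group `j` among areas
#' modally assigned to `j`. Values near 1 indicate clean assignment; empty
#' groups yield `NaN` with a warning.
#'
#' @param posteriors `N x G` posterior matrix.
#' @param labels modal assignments in `1..G`; default recomputed from
#'   `posteriors`.
#' @return Length-`G` numeric vector.
#' @export
appa <- function(posteriors, labels = NULL) {
  posteriors <- as.matrix(posteriors)
  G <- ncol(posteriors)
  if (is.null(labels)) labels <- max.col(posteriors, ties.method = "first")
  out <- vapply(seq_len(G), function(j) {
    in_j <- labels == j
    if (!any(in_j)) return(NaN)
    mean(posteriors[in_j, j])
  }, numeric(1))
  if (any(is.nan(out))) warning("empty group: APPA undefined", call. = FALSE)
  out
}

#' Odds of correct classification
#'
#' `OCC_j = [APPA_j / (1 - APPA_j)] / [pi_j / (1 - pi_j)]`: the odds of a
#' correct modal assignment relative to assignment by chance at the
#' estimated group proportion. Values above 5 are conventionally taken as
#' adequate assignment. An APPA of exactly 1 gives infinite odds; it is
#' reported capped at `9.5e7` with attribute `capped = TRUE`.
#'
#' @param appa_j average posterior probability of assignment, in (0, 1\].
#' @param pi_j estimated group proportion, in (0, 1).
#' @return Numeric vector (attribute `capped` flags APPA = 1 entries).
#' @examples
#' occ(0.9, 0.1)                 # 81
#' occ(0.9845982, 0.63199)       # ~37.2, a published six-group value
#' @export
occ <- function(appa_j, pi_j) {
  if (any(pi_j <= 0 | pi_j >= 1))
    stop("'pi_j' must lie strictly in (0, 1)", call. = FALSE)
  if (any(appa_j <= 0 | appa_j > 1))
    stop("'appa_j' must lie in (0, 1]", call. = FALSE)
  capped <- appa_j >= 1
  out <- (appa_j / (1 - appa_j)) / (pi_j / (1 - pi_j))
  out[capped] <- 9.5e7
  attr(out, "capped") <- capped
  out
}

#' Invert the odds of correct classification for the group share
#'
#' Solves `OCC_j = [APPA_j/(1-APPA_j)] / [pi_j/(1-pi_j)]` for `pi_j`:
#' `x = [APPA_j/(1-APPA_j)] / OCC_j`, `pi_j = x / (1 + x)`. Useful for
#' recovering group shares from published diagnostic tables that print APPA
#' and OCC but not the shares themselves.
#'
#' @param appa_j average posterior probability of assignment, in (0, 1).
#' @param occ_j odds of correct classification, > 0.
#' @return Estimated group proportion(s) in (0, 1).
#' @examples
#' invert_occ(0.9845982, 37.22547)   # ~0.632
#' invert_occ(0.5, 1)                # 0.5
#' @export
invert_occ <- function(appa_j, occ_j) {
  if (any(appa_j <= 0 | appa_j >= 1))
    stop("'appa_j' must lie strictly in (0, 1)", call. = FALSE)
  if (any(occ_j <= 0)) stop("'occ_j' must be > 0", call. = FALSE)
  x <- (appa_j / (1 - appa_j)) / occ_j
  x / (1 + x)
}

#' Assignment mismatch per group
#'
#' The proportion of areas hard-assigned to each group minus the estimated
#' group-membership probability `pi_j`. Sums to zero across groups.
#'
#' @param labels modal assignments in `1..G`.
#' @param pi estimated mixing proportions (length `G`).
#' @return Length-`G` numeric vector.
#' @export
mismatch <- function(labels, pi) {
  G <- length(pi)
  tabulate(labels, G) / length(labels) - pi
}

#' Diagnostic battery for a fitted multi-trajectory model
#'
#' Computes the standard latent-class enumeration diagnostics from a fit:
#' both BIC conventions (non-missing observation cells, `bic_obs`, and area
#' count, `bic_subjects`), AIC, normalised entropy, per-group APPA, OCC and
#' mismatch, and the smallest estimated group share in percent.
#'
#' @param model a [gbmt()] fit.
#' @return A list of class `gbmt_diagnostics` with fields `bic_obs`,
#'   `bic_subjects`, `aic`, `entropy`, `appa`, `occ`, `mismatch`,
#'   `smallest_group_pct`.
#' @export
fit_diagnostics <- function(model) {
  stopifnot(inherits(model, "gbmt"))
  N <- nrow(model$posterior)
  occ_v <- if (model$groups == 1L) NA_real_
           else occ(appa(model$posterior, model$labels), model$pi)
  structure(
    list(bic_obs = bic_mixture(model$logL, model$n_params, model$n_obs),
         bic_subjects = bic_mixture(model$logL, model$n_params, N),
         aic = aic_mixture(model$logL, model$n_params),
         entropy = class_entropy(model$posterior),
         appa = appa(model$posterior, model$labels),
         occ = occ_v,
         mismatch = mismatch(model$labels, model$pi),
         smallest_group_pct = 100 * min(model$pi)),
    class = "gbmt_diagnostics")
}

#' @export
print.gbmt_diagnostics <- function(x, ...) {
  cat(sprintf("BIC(obs) %.2f | BIC(areas) %.2f | AIC %.2f | entropy %.3f\n",
              x$bic_obs, x$bic_subjects, x$aic, x$entropy))
  cat("APPA:    ", paste(sprintf("%.5f", x$appa), collapse = " "), "\n")
  cat("OCC:     ", paste(signif(x$occ, 6), collapse = " "), "\n")
  cat("Mismatch:", paste(signif(x$mismatch, 4), collapse = " "), "\n")
  cat(sprintf("Smallest group: %.2f%%\n", x$smallest_group_pct))
  invisible(x)
}
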