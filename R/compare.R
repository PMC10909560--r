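#' Cross-tabulate two area classifications
#'
#' Counts areas by joint label: cell `(i, j)` is the number of areas
#' labelled `i` by the first classification and `j` by the second. Inputs
#' may be plain vectors in area order, or named vectors keyed by area id
#' (the key sets must then match exactly).
#'
#' @param labels_a,labels_b categorical label vectors over the same areas.
#' @return An `r x c` contingency table (class `table`).
#' @export
cross_tabulate <- function(labels_a, labels_b) {
  if (!is.null(names(labels_a)) && !is.null(names(labels_b))) {
    if (!setequal(names(labels_a), names(labels_b)))
      stop("the two classifications cover different area sets",
           call. = FALSE)
    labels_b <- labels_b[names(labels_a)]
  } else if (length(labels_a) != length(labels_b)) {
    stop("label vectors must cover the same areas", call. = FALSE)
  }
  table(A = labels_a, B = labels_b)
}

#' Pearson chi-square test of independence for a contingency table
#'
#' Classic Pearson test without continuity correction: expected counts
#' `E = row total x column total / N`, statistic `sum((O - E)^2 / E)`,
#' `df = (r - 1)(c - 1)`, p-value from the chi-square distribution. Empty
#' rows and columns are dropped with a warning before testing.
#'
#' @param crosstab an `r x c` count table (see [cross_tabulate()]).
#' @return A list: `chi2`, `df`, `p`, `n`, `r`, `c` (dimensions after
#'   dropping empties).
#' @export
chisq_independence <- function(crosstab) {
  crosstab <- as.matrix(crosstab)
  empty_r <- rowSums(crosstab) == 0
  empty_c <- colSums(crosstab) == 0
  if (any(empty_r) || any(empty_c)) {
    warning("dropping empty rows/columns before testing", call. = FALSE)
    crosstab <- crosstab[!empty_r, !empty_c, drop = FALSE]
  }
  if (nrow(crosstab) < 2 || ncol(crosstab) < 2)
    stop("need at least a 2 x 2 table after dropping empties",
         call. = FALSE)
  ct <- suppressWarnings(stats::chisq.test(crosstab, correct = FALSE))
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, n = sum(crosstab),
       r = nrow(crosstab), c = ncol(crosstab))
}

#' Cramer's V
#'
#' `V = sqrt(chi2 / (n * (min(r, c) - 1)))`, clipped into \[0, 1\] against
#' floating-point overshoot. A chi-square-based association measure for
#' `r x c` tables: 0 under independence, 1 for a perfect correspondence.
#'
#' @param chi2 Pearson chi-square statistic.
#' @param n total count.
#' @param r,c table dimensions (`min(r, c) >= 2`).
#' @return Scalar in \[0, 1\].
#' @export
cramers_v <- function(chi2, n, r, c) {
  if (n <= 0) stop("'n' must be > 0", call. = FALSE)
  if (min(r, c) < 2)
    stop("Cramer's V is undefined for tables with min(r, c) < 2",
         call. = FALSE)
  v <- sqrt(chi2 / (n * (min(r, c) - 1)))
  min(max(v, 0), 1)
}

#' Full association analysis of two classifications
#'
#' Cross-tabulates two label vectors and reports the Pearson chi-square
#' test of independence with Cramer's V — the standard summary when judging
#' how strongly a new area classification corresponds to an existing one.
#'
#' @inheritParams cross_tabulate
#' @return A list of class `association_result`: `crosstab`, `chi2`, `df`,
#'   `p`, `cramers_v`, `n`.
#' @export
classification_association <- function(labels_a, labels_b) {
  tab <- cross_tabulate(labels_a, labels_b)
  ct <- chisq_independence(tab)
  structure(
    list(crosstab = tab, chi2 = ct$chi2, df = ct$df, p = ct$p,
         cramers_v = cramers_v(ct$chi2, ct$n, ct$r, ct$c), n = ct$n),
    class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("Chi-square = %.1f on %d df, p %s; Cramer's V = %.4f (n = %d)\n",
              x$chi2, x$df,
              if (x$p < 1e-4) "< 0.0001" else sprintf("= %.4g", x$p),
              x$cramers_v, x$n))
  invisible(x)
}

#' Row-wise correspondence report for a cross-tabulation
#'
#' Normalises each row of a cross-tabulation to shares and flags cells of
#' exceptionally strong overlap (share above `strong`) and rows whose
#' shares are near-uniform, i.e. split evenly across the other
#' classification (all shares within `split_tol` of `1/c`). Advisory flags
#' for reading correspondence tables, not tests.
#'
#' @param crosstab an `r x c` count table.
#' @param strong share threshold for a "strong" overlap flag.
#' @param split_tol half-width of the near-uniform band.
#' @return A list: `shares` (row-normalised matrix), `strong` (logical
#'   matrix), `split` (logical per row).
#' @export
correspondence_report <- function(crosstab, strong = 0.5, split_tol = 0.1) {
  m <- as.matrix(crosstab)
  if (!length(m)) stop("empty table", call. = FALSE)
  shares <- m / pmax(rowSums(m), 1)
  shares[rowSums(m) == 0, ] <- NA_real_
  uniform <- 1 / ncol(m)
  split <- apply(shares, 1L, function(r)
    all(!is.na(r)) && all(abs(r - uniform) <= split_tol))
  list(shares = shares, strong = !is.na(shares) & shares > strong,
       split = split)
}

#' Transfer labels across geographies by majority areal weight
#'
#' Assigns each target area the label of the source contributing the
#' largest areal weight into it (equal-split weights where the lookup
#' carries none). Ties break to the lowest label after sorting. This is the
#' pragmatic rule for carrying a categorical classification from one
#' boundary system to another before cross-tabulation.
#'
#' @param labels named vector of source labels (names = source ids), or a
#'   data frame with `area_id` and `label` columns.
#' @param lookup lookup data frame as in [convert_counts()].
#' @return Named character vector of target labels.
#' @export
transfer_labels <- function(labels, lookup) {
  if (is.data.frame(labels)) {
    lab <- as.character(labels$label)
    names(lab) <- as.character(labels$area_id)
    labels <- lab
  }
  if (is.null(lookup$weight)) lookup$weight <- NA_real_
  src <- as.character(lookup$source_id)
  missing_src <- setdiff(unique(src), names(labels))
  if (length(missing_src))
    stop("sources without labels: ", paste(missing_src, collapse = ", "),
         call. = FALSE)
  # resolve equal-split weights
  w <- lookup$weight
  for (s in unique(src[is.na(w)])) {
    idx <- which(src == s)
    if (all(is.na(lookup$weight[idx]))) w[idx] <- 1 / length(idx)
  }
  tgt <- as.character(lookup$target_id)
  out <- vapply(sort(unique(tgt)), function(tid) {
    idx <- which(tgt == tid)
    lab <- labels[src[idx]]
    mass <- tapply(w[idx], lab, sum)
    mx <- names(mass)[mass == max(mass)]
    sort(mx)[1]
  }, character(1))
  out
}
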