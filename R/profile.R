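#' Classify-analyse cluster profiling
#'
#' Profiles a hard classification against an attribute table: per-cluster
#' means of every attribute (ignoring missing values), cluster shares in
#' percent, and a one-way ANOVA per attribute testing equality of cluster
#' means. With `weights = "posterior"` the means are posterior-weighted
#' instead of hard-assigned (classify-analyse ignores assignment
#' uncertainty; the weighted variant is offered for sensitivity checks).
#'
#' @param labels integer cluster labels in `1..G`, or a [gbmt()] fit (its
#'   modal labels are used).
#' @param attributes data frame of numeric attributes, one row per area in
#'   label order, or with an `area_id` column matching `names(labels)`.
#' @param weights `"hard"` (default) or `"posterior"` (requires a `gbmt`
#'   fit as `labels`).
#' @param anova_alpha significance level reported against (default 0.05).
#' @param bonferroni apply a Bonferroni correction across attributes
#'   (off by default).
#' @return A list of class `cluster_profile`: `means` (attribute x cluster
#'   matrix), `shares_pct`, `sizes`, `anova` (data frame: attribute, F,
#'   df1, df2, p, significant).
#' @export
cluster_profile <- function(labels, attributes,
                            weights = c("hard", "posterior"),
                            anova_alpha = 0.05, bonferroni = FALSE) {
  weights <- match.arg(weights)
  post <- NULL
  if (inherits(labels, "gbmt")) {
    post <- labels$posterior
    labels <- labels$labels
  }
  if (weights == "posterior" && is.null(post))
    stop("posterior weighting needs a fitted 'gbmt' object", call. = FALSE)
  if ("area_id" %in% names(attributes))
    attributes <- attributes[, setdiff(names(attributes), "area_id"),
                             drop = FALSE]
  if (nrow(attributes) != length(labels))
    stop("attribute rows must match the number of classified areas",
         call. = FALSE)
  G <- max(labels)
  sizes <- tabulate(labels, G)
  shares <- 100 * sizes / length(labels)
  means <- matrix(NA_real_, ncol(attributes), G,
                  dimnames = list(names(attributes), paste0("cluster", 1:G)))
  for (a in seq_along(attributes)) {
    x <- as.numeric(attributes[[a]])
    for (g in seq_len(G)) {
      if (weights == "hard") {
        xs <- x[labels == g]
        means[a, g] <- if (length(xs)) mean(xs, na.rm = TRUE) else NA_real_
      } else {
        w <- post[, g]
        ok <- !is.na(x)
        means[a, g] <- sum(w[ok] * x[ok]) / sum(w[ok])
      }
    }
  }
  av <- do.call(rbind, lapply(seq_along(attributes), function(a) {
    res <- tryCatch(anova_clusters(labels, as.numeric(attributes[[a]])),
                    error = function(e) list(F = NA, df = c(NA, NA), p = NA))
    data.frame(attribute = names(attributes)[a], F = res$F,
               df1 = res$df[1], df2 = res$df[2], p = res$p)
  }))
  alpha_eff <- if (bonferroni) anova_alpha / nrow(av) else anova_alpha
  av$significant <- !is.na(av$p) & av$p < alpha_eff
  structure(list(means = means, shares_pct = shares, sizes = sizes,
                 anova = av, alpha = alpha_eff),
            class = "cluster_profile")
}

#' @export
print.cluster_profile <- function(x, ...) {
  cat("Cluster shares (%):",
      paste(sprintf("%.1f", x$shares_pct), collapse = " "), "\n")
  cat("Means by cluster:\n")
  print(round(x$means, 2))
  cat(sprintf("ANOVA (alpha = %g):\n", x$alpha))
  print(x$anova, row.names = FALSE)
  invisible(x)
}

#' One-way ANOVA of an attribute across clusters
#'
#' Fixed-effects one-way analysis of variance of `x` on the cluster factor:
#' `F` is the between-cluster mean square over the within-cluster mean
#' square on `(G - 1, N - G)` degrees of freedom. Fitted via [stats::lm()].
#' Zero within-cluster variance with unequal means is reported as `p = 0`
#' with a `degenerate` flag.
#'
#' @param labels cluster labels (>= 2 non-empty clusters after removing
#'   missing `x`).
#' @param x numeric attribute; `NA` dropped pairwise with its label.
#' @return A list: `F`, `df` (length 2), `p`, `degenerate`.
#' @examples
#' anova_clusters(c(1, 1, 1, 2, 2, 2), c(1, 2, 3, 4, 5, 6))  # F = 13.5
#' @export
anova_clusters <- function(labels, x) {
  ok <- !is.na(x) & !is.na(labels)
  x <- x[ok]; labels <- factor(labels[ok])
  if (nlevels(labels) < 2 || length(x) < 3)
    stop("need >= 2 non-empty clusters and >= 3 values", call. = FALSE)
  fit <- stats::lm(x ~ labels)
  # degenerate (zero-variance) layouts are handled explicitly below
  an <- suppressWarnings(stats::anova(fit))
  Fv <- an[1, "F value"]; p <- an[1, "Pr(>F)"]
  degenerate <- FALSE
  eps <- 1e-12 * max(an[1, "Mean Sq"], .Machine$double.xmin)
  if (an[2, "Mean Sq"] <= eps && an[1, "Mean Sq"] > 0) {
    Fv <- Inf; p <- 0; degenerate <- TRUE
  }
  if (an[1, "Mean Sq"] <= .Machine$double.xmin) { Fv <- 0; p <- 1 }
  list(F = Fv, df = c(an[1, "Df"], an[2, "Df"]), p = p,
       degenerate = degenerate)
}

#' Geographic distribution of clusters
#'
#' For each cluster: the percentage of its areas flagged urban, and the
#' percentage falling in each region (rows over regions sum to 100).
#'
#' @param labels cluster labels in `1..G`.
#' @param regions character/factor region tag per area.
#' @param urban logical urban flag per area (optional).
#' @param region_levels admissible region tags; unknown tags are an error.
#'   Default: the distinct observed tags.
#' @return A list: `region_pct` (cluster x region matrix), `urban_pct`
#'   (per cluster, or `NULL`).
#' @export
geography_summary <- function(labels, regions, urban = NULL,
                              region_levels = NULL) {
  if (length(regions) != length(labels))
    stop("'regions' must tag every classified area", call. = FALSE)
  regions <- as.character(regions)
  if (is.null(region_levels)) region_levels <- sort(unique(regions))
  unknown <- setdiff(unique(regions), region_levels)
  if (length(unknown))
    stop("unknown region tags: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  G <- max(labels)
  tab <- table(factor(labels, levels = 1:G),
               factor(regions, levels = region_levels))
  region_pct <- 100 * prop.table(tab + 0, margin = 1)
  region_pct[is.nan(region_pct)] <- NA_real_
  urban_pct <- NULL
  if (!is.null(urban)) {
    if (length(urban) != length(labels))
      stop("'urban' must flag every classified area", call. = FALSE)
    urban_pct <- vapply(1:G, function(g) {
      in_g <- labels == g
      if (!any(in_g)) return(NA_real_)
      100 * mean(as.logical(urban[in_g]))
    }, numeric(1))
  }
  list(region_pct = as.matrix(region_pct), urban_pct = urban_pct)
}
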