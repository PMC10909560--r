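#' Indicator panel container
#'
#' An `indicator_panel` holds an area x time x indicator array of percentage
#' values in \[0, 100\] together with a missingness mask. It is the observed
#' data object consumed by [gbmt()]: `values[i, t, k]` is the percentage for
#' area `i`, census year `t`, indicator `k`, and `NA` marks a cell that was
#' not observed (e.g. the four age/tenure indicators at the first census, or
#' a share whose denominator was zero).
#'
#' @param values numeric array, `n_areas x n_years x n_indicators`. `NA`
#'   entries are treated as missing.
#' @param areas character vector of area identifiers (defaults to
#'   `"A1".."An"`).
#' @param years numeric vector of census years labelling the time axis
#'   (defaults to `seq_len(T)`). Model time is always coded `0, 1, ...`
#'   in the order of `years`.
#' @param indicators character vector of indicator names.
#'
#' @return An object of class `indicator_panel`: a list with elements
#'   `values` (the array, with dimnames), `areas`, `years`, `indicators`.
#' @examples
#' v <- array(50, dim = c(3, 4, 2))
#' p <- indicator_panel(v, years = c(1981, 1991, 2001, 2011),
#'                      indicators = c("pct_internal", "pct_international"))
#' dim(p$values)
#' @export
indicator_panel <- function(values, areas = NULL, years = NULL,
                            indicators = NULL) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("'values' must be a 3-dimensional array (area x year x indicator)",
         call. = FALSE)
  d <- dim(values)
  if (is.null(areas)) areas <- paste0("A", seq_len(d[1]))
  if (is.null(years)) years <- seq_len(d[2])
  if (is.null(indicators)) indicators <- paste0("ind", seq_len(d[3]))
  if (length(areas) != d[1] || length(years) != d[2] ||
      length(indicators) != d[3])
    stop("dimnames lengths do not match the dimensions of 'values'",
         call. = FALSE)
  rng <- range(values, na.rm = TRUE)
  if (any(is.finite(rng)) && (rng[1] < 0 || rng[2] > 100))
    stop("non-missing panel values must lie in [0, 100]", call. = FALSE)
  storage.mode(values) <- "double"
  dimnames(values) <- list(areas, years, indicators)
  structure(
    list(values = values, areas = as.character(areas),
         years = as.numeric(years), indicators = as.character(indicators)),
    class = "indicator_panel")
}

#' @export
print.indicator_panel <- function(x, ...) {
  d <- dim(x$values)
  n_miss <- sum(is.na(x$values))
  cat(sprintf("Indicator panel: %d areas x %d years x %d indicators\n",
              d[1], d[2], d[3]))
  cat("Years:      ", paste(x$years, collapse = ", "), "\n")
  cat("Indicators: ", paste(x$indicators, collapse = ", "), "\n")
  cat(sprintf("Missing cells: %d of %d (%.1f%%)\n", n_miss,
              prod(d), 100 * n_miss / prod(d)))
  invisible(x)
}

#' @export
dim.indicator_panel <- function(x) dim(x$values)

# coded time axis: 0, 1, ..., T-1 regardless of the year labels
panel_time <- function(panel) seq_along(panel$years) - 1

# area x (T*K) matrix view used by the EM routines; columns vary time
# fastest within indicator
panel_matrix <- function(panel) {
  d <- dim(panel$values)
  matrix(panel$values, nrow = d[1], ncol = d[2] * d[3],
         dimnames = list(panel$areas, NULL))
}

as_indicator_panel <- function(x) {
  if (inherits(x, "indicator_panel")) return(x)
  stop("expected an 'indicator_panel' object", call. = FALSE)
}
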