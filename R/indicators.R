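#' Percentage share of a count in a denominator
#'
#' The elementary operation behind all six migration indicators:
#' `100 * numerator / denominator`, with a zero denominator yielding `NA`
#' (an undefined share, distinct from a zero share).
#'
#' @param numerator,denominator nonnegative counts (vectorised).
#' @return Numeric vector of percentages, `NA` where the denominator is 0 or
#'   either input is `NA`.
#' @examples
#' share_pct(150, 1000)  # 15
#' share_pct(7, 0)       # NA
#' @export
share_pct <- function(numerator, denominator) {
  if (any(numerator < 0, na.rm = TRUE) || any(denominator < 0, na.rm = TRUE))
    stop("counts must be nonnegative", call. = FALSE)
  out <- 100 * numerator / denominator
  out[!is.na(denominator) & denominator == 0] <- NA_real_
  out
}

#' Names of the count columns expected by [build_panel()]
#' @keywords internal
count_columns <- function() {
  c("usual_residents", "internal_inmovers", "international_inmovers",
    "inmovers_18_24", "inmovers_65plus", "inmover_households",
    "inmover_households_owner", "inmover_households_social")
}

#' Build the six migration indicators from census-style count tables
#'
#' Computes, for every (area, year) record, the six ward-level migration
#' indicators used by the multi-trajectory classification:
#'
#' 1. internal in-movers as a percentage of usual residents,
#' 2. international in-movers as a percentage of usual residents,
#' 3. in-movers aged 18-24 as a percentage of all (internal + international)
#'    in-movers,
#' 4. in-movers aged 65+ as a percentage of all in-movers,
#' 5. owner-occupying in-moving households as a percentage of all in-moving
#'    households,
#' 6. socially renting in-moving households as a percentage of all in-moving
#'    households.
#'
#' Count columns absent for a year (for instance age and tenure detail at an
#' early census) propagate to missing indicator cells rather than zeros, and
#' a zero denominator likewise yields a missing share. An optional
#' `adjust_factor` column pre-scales the internal in-mover count per record
#' (a hook for corrections for incompletely stated origin addresses); the
#' default is no adjustment.
#'
#' @param counts data frame with one row per (area, year): columns
#'   `area_id`, `year`, the eight count columns of [count_columns()]
#'   (missing counts may be `NA`), and optionally `adjust_factor`.
#' @return An [indicator_panel()] with the six indicators, areas sorted by
#'   first appearance and years ascending.
#' @examples
#' counts <- data.frame(area_id = "A1", year = 2011, usual_residents = 1000,
#'   internal_inmovers = 80, international_inmovers = 20,
#'   inmovers_18_24 = 70, inmovers_65plus = 5,
#'   inmover_households = 50, inmover_households_owner = 20,
#'   inmover_households_social = 10)
#' build_panel(counts)$values[1, 1, ]
#' @export
build_panel <- function(counts) {
  needed <- c("area_id", "year")
  if (!all(needed %in% names(counts)))
    stop("'counts' must have 'area_id' and 'year' columns", call. = FALSE)
  for (col in count_columns())
    if (is.null(counts[[col]])) counts[[col]] <- NA_real_
  key <- paste(counts$area_id, counts$year, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (area_id, year) records: ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  num <- counts[count_columns()]
  if (any(num < 0, na.rm = TRUE))
    stop("counts must be nonnegative", call. = FALSE)
  adj <- counts$adjust_factor
  if (is.null(adj)) adj <- rep(1, nrow(counts))
  internal <- counts$internal_inmovers * adj
  intl <- counts$international_inmovers
  movers <- internal + intl
  bad_age <- !is.na(counts$inmovers_18_24) & !is.na(movers) &
    counts$inmovers_18_24 > movers + 1e-9
  if (any(bad_age))
    stop("inmovers_18_24 exceeds total in-movers for: ",
         paste(counts$area_id[bad_age], counts$year[bad_age],
               collapse = "; "), call. = FALSE)
  ind <- cbind(
    pct_internal      = share_pct(internal, counts$usual_residents),
    pct_international = share_pct(intl, counts$usual_residents),
    pct_age_18_24     = share_pct(counts$inmovers_18_24, movers),
    pct_age_65plus    = share_pct(counts$inmovers_65plus, movers),
    pct_owner         = share_pct(counts$inmover_households_owner,
                                  counts$inmover_households),
    pct_social        = share_pct(counts$inmover_households_social,
                                  counts$inmover_households))
  areas <- unique(as.character(counts$area_id))
  years <- sort(unique(counts$year))
  values <- array(NA_real_, dim = c(length(areas), length(years), 6L))
  ai <- match(as.character(counts$area_id), areas)
  yi <- match(counts$year, years)
  for (k in 1:6)
    values[cbind(ai, yi, k)] <- ind[, k]
  indicator_panel(values, areas = areas, years = years,
                  indicators = colnames(ind))
}
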