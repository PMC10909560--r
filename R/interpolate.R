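#' Convert count tables between boundary systems by areal weighting
#'
#' Transfers counts from a source geography to a target geography using a
#' lookup table of overlap weights: each target receives
#' `sum(weight * source value)` over the sources mapping into it. Sources
#' whose lookup rows carry no weights are split equally across their targets
#' (weight `1/m` for `m` targets) — the fallback used when conversion tables
#' state correspondences but no proportions. Converted counts stay
#' fractional; shares computed downstream are scale-free, so no rounding is
#' applied.
#'
#' A source must be consistently weighted or consistently weight-free;
#' mixing the two regimes within one source is an error, as is a source
#' present in `values` but absent from the lookup.
#'
#' @param values data frame of source counts: column `area_id` plus any
#'   number of numeric count columns.
#' @param lookup data frame with columns `source_id`, `target_id` and
#'   optional `weight` (nonnegative; per-source weights must sum to 1 within
#'   `1e-9` where present; `NA` weight means "no proportion stated").
#' @return Data frame of target counts with the same count columns, one row
#'   per target id (sorted), named `area_id`.
#' @examples
#' v <- data.frame(area_id = "A", pop = 100)
#' lk <- data.frame(source_id = "A", target_id = c("X", "Y"),
#'                  weight = c(0.3, 0.7))
#' convert_counts(v, lk)
#' @export
convert_counts <- function(values, lookup) {
  if (!"area_id" %in% names(values))
    stop("'values' must have an 'area_id' column", call. = FALSE)
  if (!all(c("source_id", "target_id") %in% names(lookup)))
    stop("'lookup' needs 'source_id' and 'target_id' columns", call. = FALSE)
  if (is.null(lookup$weight)) lookup$weight <- NA_real_
  if (anyDuplicated(paste(lookup$source_id, lookup$target_id, sep = "\r")))
    stop("duplicate (source_id, target_id) pairs in lookup", call. = FALSE)
  src <- as.character(values$area_id)
  missing_src <- setdiff(src, as.character(lookup$source_id))
  if (length(missing_src))
    stop("sources absent from lookup: ",
         paste(missing_src, collapse = ", "), call. = FALSE)
  lookup <- lookup[as.character(lookup$source_id) %in% src, , drop = FALSE]
  # resolve weights per source: proportional or equal split, never mixed
  w <- numeric(nrow(lookup))
  for (s in unique(as.character(lookup$source_id))) {
    idx <- which(as.character(lookup$source_id) == s)
    ws <- lookup$weight[idx]
    if (all(is.na(ws))) {
      w[idx] <- 1 / length(idx)
    } else if (any(is.na(ws))) {
      stop("source '", s, "' mixes weighted and weight-free rows",
           call. = FALSE)
    } else {
      if (any(ws < 0)) stop("negative weight for source '", s, "'",
                            call. = FALSE)
      if (abs(sum(ws) - 1) > 1e-9)
        stop("weights for source '", s, "' sum to ", format(sum(ws)),
             ", not 1", call. = FALSE)
      w[idx] <- ws
    }
  }
  count_cols <- setdiff(names(values), "area_id")
  si <- match(as.character(lookup$source_id), src)
  targets <- sort(unique(as.character(lookup$target_id)))
  ti <- match(as.character(lookup$target_id), targets)
  out <- data.frame(area_id = targets)
  for (col in count_cols) {
    contrib <- w * values[[col]][si]
    out[[col]] <- as.numeric(
      rowsum(contrib, group = ti, reorder = TRUE))
  }
  out
}

#' Validate a boundary conversion against reference output
#'
#' Compares converted target counts against a reference table (for instance
#' an authoritative pre-built conversion) and flags areas whose relative
#' discrepancy on any count column exceeds `tolerance`. The relative
#' discrepancy for an area is `max(|candidate - reference| /
#' max(|reference|, 1))` over count columns, so zero-count areas are judged
#' on an absolute scale.
#'
#' @param candidate,reference data frames with `area_id` plus identical
#'   count columns over the same area set.
#' @param tolerance nonnegative relative tolerance.
#' @return A list with `flagged` (data frame: `area_id`, `discrepancy` for
#'   areas above tolerance), `n_checked`, `n_flagged`, `max_discrepancy`.
#' @export
validate_conversion <- function(candidate, reference, tolerance) {
  if (tolerance < 0) stop("'tolerance' must be >= 0", call. = FALSE)
  ids_c <- sort(as.character(candidate$area_id))
  ids_r <- sort(as.character(reference$area_id))
  if (!identical(ids_c, ids_r))
    stop("candidate and reference cover different area sets", call. = FALSE)
  cols <- setdiff(intersect(names(candidate), names(reference)), "area_id")
  if (!length(cols)) stop("no shared count columns to compare", call. = FALSE)
  candidate <- candidate[order(as.character(candidate$area_id)), ]
  reference <- reference[order(as.character(reference$area_id)), ]
  rel <- sapply(cols, function(col) {
    ref <- reference[[col]]
    abs(candidate[[col]] - ref) / pmax(abs(ref), 1)
  })
  rel <- matrix(rel, nrow = nrow(candidate))
  disc <- apply(rel, 1L, max)
  flag <- disc > tolerance
  list(flagged = data.frame(area_id = ids_c[flag], discrepancy = disc[flag]),
       n_checked = length(disc), n_flagged = sum(flag),
       max_discrepancy = if (length(disc)) max(disc) else 0)
}
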