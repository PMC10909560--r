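#' Specification of a synthetic indicator panel
#'
#' Defines the latent-group structure from which [simulate_panel()] draws:
#' group mixing proportions, per-group polynomial mean trajectories for each
#' indicator on the percentage scale, Gaussian noise scales, and an
#' availability mask saying which indicator-year cells are observable.
#'
#' The defaults emulate the study design the package targets: roughly ten
#' thousand wards observed at the four decadal censuses 1981-2011 (time coded
#' 0..3), six migration indicators of which the two in-mover shares are
#' available at every census while the four age/tenure composition indicators
#' are unavailable at the first, and six latent clusters whose mixing
#' proportions follow the published cluster shares. The default trajectories
#' sketch the six named cluster profiles (steadily increasing, two low-stable
#' variants, increasing-young, high-international, high-but-declining); they
#' are plausible percentage paths, not estimates.
#'
#' @param n_areas number of areas.
#' @param n_timepoints number of census years `T` (time coded `0..T-1`).
#' @param group_props vector of `G` mixing proportions summing to 1.
#' @param traj_coeffs `G x K x (max_order+1)` array of polynomial
#'   coefficients on the percentage scale; `traj_coeffs[g, k, j]` multiplies
#'   `t^(j-1)`.
#' @param noise_sd positive noise standard deviations in percentage points:
#'   either a length-`K` vector (shared across groups) or a `G x K` matrix.
#' @param availability `K x T` logical matrix; `FALSE` cells are generated as
#'   missing. Default: indicators 1-2 always observed, indicators 3+ missing
#'   at the first time point (when `K >= 3`).
#' @param years year labels of length `n_timepoints`.
#' @param seed integer RNG seed.
#'
#' @return A list of class `sim_spec`.
#' @seealso [simulate_panel()]
#' @export
sim_spec <- function(n_areas = 9976,
                     n_timepoints = 4,
                     group_props = c(0.107, 0.213, 0.632, 0.024, 0.005, 0.019),
                     traj_coeffs = NULL,
                     noise_sd = NULL,
                     availability = NULL,
                     years = NULL,
                     seed = 1L) {
  if (n_areas < 1 || n_timepoints < 1)
    stop("'n_areas' and 'n_timepoints' must be positive", call. = FALSE)
  stopifnot_prob_vector(group_props, "group_props")
  G <- length(group_props)
  if (is.null(traj_coeffs)) {
    if (G != 6 || n_timepoints != 4)
      stop("default 'traj_coeffs' require G = 6 and n_timepoints = 4; ",
           "supply trajectories explicitly", call. = FALSE)
    traj_coeffs <- default_trajectories()
  }
  if (length(dim(traj_coeffs)) != 3L || dim(traj_coeffs)[1] != G)
    stop("'traj_coeffs' must be a G x K x (order+1) array", call. = FALSE)
  if (any(!is.finite(traj_coeffs)))
    stop("'traj_coeffs' must be finite", call. = FALSE)
  K <- dim(traj_coeffs)[2]
  if (dim(traj_coeffs)[3] > n_timepoints)
    stop("polynomial order must not exceed n_timepoints - 1", call. = FALSE)
  if (is.null(noise_sd)) {
    if (K != 6)
      stop("default 'noise_sd' requires K = 6; supply noise scales",
           call. = FALSE)
    noise_sd <- c(1.5, 0.8, 5, 3, 6, 5)
  }
  if (is.matrix(noise_sd)) {
    if (!all(dim(noise_sd) == c(G, K)))
      stop("matrix 'noise_sd' must be G x K", call. = FALSE)
  } else if (length(noise_sd) != K) {
    stop("'noise_sd' must have one entry per indicator", call. = FALSE)
  }
  if (any(noise_sd <= 0)) stop("'noise_sd' must be > 0", call. = FALSE)
  if (is.null(availability)) {
    availability <- matrix(TRUE, K, n_timepoints)
    if (K >= 3 && n_timepoints > 1) availability[3:K, 1] <- FALSE
  }
  if (!is.matrix(availability) || !all(dim(availability) == c(K, n_timepoints)))
    stop("'availability' must be a K x T logical matrix", call. = FALSE)
  if (any(rowSums(availability) < 1))
    stop("every indicator needs at least one observable time point",
         call. = FALSE)
  if (is.null(years)) {
    years <- if (n_timepoints == 4) c(1981, 1991, 2001, 2011)
             else seq_len(n_timepoints)
  }
  structure(
    list(n_areas = as.integer(n_areas),
         n_timepoints = as.integer(n_timepoints),
         group_props = as.numeric(group_props),
         traj_coeffs = traj_coeffs,
         noise_sd = noise_sd,
         availability = availability,
         years = as.numeric(years),
         seed = as.integer(seed)),
    class = "sim_spec")
}

# hand-sketched mean paths for the six named clusters, coded time 0..3;
# indicator order: internal %, international %, age 18-24 %, age 65+ %,
# owner-occupier %, social-housing %
default_trajectories <- function() {
  K <- 6
  tc <- array(0, dim = c(6, K, 4))
  set_traj <- function(g, k, coefs) tc[g, k, seq_along(coefs)] <<- coefs
  # 1 steadily increasing migration
  set_traj(1, 1, c(9, 1.4));   set_traj(1, 2, c(1.2, 0.35))
  set_traj(1, 3, c(30));       set_traj(1, 4, c(6, -0.5))
  set_traj(1, 5, c(40));       set_traj(1, 6, c(15))
  # 2 low and stable - social housing
  set_traj(2, 1, c(7));        set_traj(2, 2, c(0.5))
  set_traj(2, 3, c(18));       set_traj(2, 4, c(9))
  set_traj(2, 5, c(40));       set_traj(2, 6, c(32))
  # 3 low and stable - older owning
  set_traj(3, 1, c(7.5));      set_traj(3, 2, c(0.5))
  set_traj(3, 3, c(16));       set_traj(3, 4, c(11))
  set_traj(3, 5, c(60));       set_traj(3, 6, c(8))
  # 4 increasing, young migration
  set_traj(4, 1, c(11, 3.7));  set_traj(4, 2, c(1, 1.6))
  set_traj(4, 3, c(45, 8));    set_traj(4, 4, c(6, -1.3))
  set_traj(4, 5, c(30, -3));   set_traj(4, 6, c(12))
  # 5 high international migration (international share peaks mid-period)
  set_traj(5, 1, c(16));       set_traj(5, 2, c(6, 2, -0.5))
  set_traj(5, 3, c(30));       set_traj(5, 4, c(5, 0.5))
  set_traj(5, 5, c(25));       set_traj(5, 6, c(10))
  # 6 high but declining migration
  set_traj(6, 1, c(15, -1.5)); set_traj(6, 2, c(4, -1))
  set_traj(6, 3, c(25));       set_traj(6, 4, c(7))
  set_traj(6, 5, c(45));       set_traj(6, 6, c(8))
  tc
}

#' Simulate an indicator panel with known latent groups
#'
#' Draws a group label for every area from the spec's mixing proportions,
#' evaluates each group's polynomial mean trajectory at coded times
#' `0..T-1`, adds Gaussian noise, clips to \[0, 100\], and blanks the cells
#' the availability mask marks unobservable. The whole draw is governed by
#' `spec$seed`: identical specs give bitwise-identical panels.
#'
#' @param spec a [sim_spec()] object.
#' @return A list of class `sim_panel` with elements `panel` (an
#'   [indicator_panel()]), `true_labels` (integer group per area), `spec`,
#'   and `n_clipped` (count of values clipped to the \[0, 100\] bounds).
#' @examples
#' sp <- sim_spec(n_areas = 50, group_props = c(0.5, 0.5),
#'                traj_coeffs = array(c(10, 40), dim = c(2, 1, 1)),
#'                noise_sd = 1, availability = matrix(TRUE, 1, 4), seed = 7)
#' sim <- simulate_panel(sp)
#' table(sim$true_labels)
#' @export
simulate_panel <- function(spec) {
  if (!inherits(spec, "sim_spec")) spec <- do.call(sim_spec, spec)
  N <- spec$n_areas; Tn <- spec$n_timepoints
  G <- length(spec$group_props); K <- dim(spec$traj_coeffs)[2]
  set.seed(spec$seed)
  labels <- sample.int(G, N, replace = TRUE, prob = spec$group_props)
  time <- seq_len(Tn) - 1
  # mu[g, t, k]
  mu <- array(0, dim = c(G, Tn, K))
  ord1 <- dim(spec$traj_coeffs)[3]
  X <- poly_design(time, ord1 - 1L)
  for (g in seq_len(G)) for (k in seq_len(K))
    mu[g, , k] <- X %*% spec$traj_coeffs[g, k, ]
  sd_gk <- if (is.matrix(spec$noise_sd)) spec$noise_sd
           else matrix(spec$noise_sd, G, K, byrow = TRUE)
  # noise drawn area-major so a fixed seed pins the full panel
  eps <- array(stats::rnorm(N * Tn * K), dim = c(Tn, K, N))
  values <- array(NA_real_, dim = c(N, Tn, K))
  for (i in seq_len(N)) {
    g <- labels[i]
    values[i, , ] <- mu[g, , ] + eps[, , i] * rep(sd_gk[g, ], each = Tn)
  }
  n_clipped <- sum(values < 0 | values > 100, na.rm = TRUE)
  values[values < 0] <- 0
  values[values > 100] <- 100
  for (k in seq_len(K)) for (t in seq_len(Tn))
    if (!spec$availability[k, t]) values[, t, k] <- NA_real_
  panel <- indicator_panel(values, years = spec$years,
                           indicators = default_indicator_names(K))
  structure(list(panel = panel, true_labels = labels, spec = spec,
                 n_clipped = n_clipped),
            class = "sim_panel")
}

default_indicator_names <- function(K) {
  nm <- c("pct_internal", "pct_international", "pct_age_18_24",
          "pct_age_65plus", "pct_owner", "pct_social")
  if (K <= 6) nm[seq_len(K)] else c(nm, paste0("ind", 7:K))
}

#' @export
print.sim_panel <- function(x, ...) {
  cat(sprintf("Simulated panel: %d areas, %d latent groups (seed %d)\n",
              x$spec$n_areas, length(x$spec$group_props), x$spec$seed))
  cat("Label shares:",
      paste(sprintf("%.3f", tabulate(x$true_labels,
                                     length(x$spec$group_props)) /
                      x$spec$n_areas), collapse = " "), "\n")
  print(x$panel)
  invisible(x)
}

#' Generate a synthetic source-to-target area lookup table
#'
#' Builds a random boundary-conversion lookup in which every source area maps
#' to between one and three target areas. With `weighted = TRUE` each
#' source's weights are positive and sum to 1 (the areal-weighting regime);
#' with `weighted = FALSE` the weight column is `NA` throughout, exercising
#' the equal-split fallback of [convert_counts()].
#'
#' @param n_source,n_target numbers of source and target areas (>= 1).
#' @param seed integer RNG seed.
#' @param weighted emit proportional weights (`TRUE`) or weight-free rows.
#' @return A data frame with columns `source_id`, `target_id`, `weight`.
#' @export
simulate_area_lookup <- function(n_source, n_target, seed = 1L,
                                 weighted = TRUE) {
  if (n_source < 1 || n_target < 1)
    stop("'n_source' and 'n_target' must be >= 1", call. = FALSE)
  set.seed(as.integer(seed))
  rows <- lapply(seq_len(n_source), function(s) {
    m <- sample.int(min(3L, n_target), 1L)
    tg <- sample.int(n_target, m)
    w <- if (weighted) {
      u <- stats::runif(m) + 0.05   # bounded away from 0
      u / sum(u)
    } else rep(NA_real_, m)
    data.frame(source_id = paste0("S", s), target_id = paste0("T", tg),
               weight = w)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a pair of synthetic area classifications with tunable association
#'
#' Produces two categorical label vectors over the same areas whose
#' association interpolates between independence (`association = 0`) and a
#' deterministic surjection of the first labelling onto the second
#' (`association = 1`; with `r == c` this is a bijection, so Cramer's V
#' equals 1). Each area's second label follows the surjection with
#' probability `association` and is drawn uniformly otherwise.
#'
#' @param n_areas number of areas.
#' @param r,c numbers of categories of the two classifications (>= 2).
#' @param association real in \[0, 1\].
#' @param seed integer RNG seed.
#' @return A list with integer vectors `labels_a` (values in `1..r`) and
#'   `labels_b` (values in `1..c`).
#' @seealso [classification_association()]
#' @export
simulate_paired_classifications <- function(n_areas, r, c, association,
                                            seed = 1L) {
  if (r < 2 || c < 2) stop("'r' and 'c' must be >= 2", call. = FALSE)
  if (!is.finite(association) || association < 0 || association > 1)
    stop("'association' must lie in [0, 1]", call. = FALSE)
  set.seed(as.integer(seed))
  a <- sample.int(r, n_areas, replace = TRUE)
  mapped <- ((a - 1L) %% c) + 1L
  random_b <- sample.int(c, n_areas, replace = TRUE)
  use_map <- stats::runif(n_areas) < association
  list(labels_a = a, labels_b = ifelse(use_map, mapped, random_b))
}
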