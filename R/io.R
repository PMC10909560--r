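#' Read and write indicator panels as long-format CSV
#'
#' The on-disk dialect is one row per (area, year, indicator) cell:
#' columns `area_id, year, indicator, value, missing_flag` (UTF-8, `.`
#' decimal, header required). Missing cells carry an empty `value` and
#' `missing_flag = 1`. `write_panel()` followed by `read_panel()` is the
#' identity on canonical panels.
#'
#' @param path CSV file path.
#' @return `read_panel()`: an [indicator_panel()].
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("area_id", "year", "indicator", "value", "missing_flag")
  if (!all(needed %in% names(df)))
    stop("panel CSV must have columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  bad <- !is.na(df$value) & (df$value < 0 | df$value > 100)
  if (any(bad))
    stop("panel values outside [0, 100] at rows: ",
         paste(utils::head(which(bad) + 1L, 10), collapse = ", "),
         call. = FALSE)
  areas <- unique(df$area_id)
  years <- sort(unique(df$year))
  indicators <- unique(df$indicator)
  values <- array(NA_real_, dim = c(length(areas), length(years),
                                    length(indicators)))
  idx <- cbind(match(df$area_id, areas), match(df$year, years),
               match(df$indicator, indicators))
  v <- df$value
  v[df$missing_flag == 1] <- NA_real_
  values[idx] <- v
  indicator_panel(values, areas = areas, years = years,
                  indicators = indicators)
}

#' @rdname read_panel
#' @param panel an [indicator_panel()].
#' @export
write_panel <- function(panel, path) {
  panel <- as_indicator_panel(panel)
  d <- dim(panel$values)
  grid <- expand.grid(ai = seq_len(d[1]), yi = seq_len(d[2]),
                      ki = seq_len(d[3]))
  v <- panel$values[as.matrix(grid)]
  df <- data.frame(area_id = panel$areas[grid$ai],
                   year = panel$years[grid$yi],
                   indicator = panel$indicators[grid$ki],
                   value = v,
                   missing_flag = as.integer(is.na(v)))
  # keep the panel's own area/indicator order so read(write(x)) = x
  df <- df[order(grid$ai, grid$yi, grid$ki), ]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a boundary lookup table
#'
#' Expects columns `source_id,target_id[,weight]`; a missing weight column
#' (or `NA` weights) marks sources for the equal-split fallback.
#' @param path CSV file path.
#' @return Data frame with `source_id`, `target_id`, `weight`.
#' @export
read_lookup <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("source_id", "target_id") %in% names(df)))
    stop("lookup CSV needs source_id and target_id columns", call. = FALSE)
  if (is.null(df$weight)) df$weight <- NA_real_
  df
}

#' Read / write classification label tables (`area_id,label`)
#' @param path CSV file path.
#' @return `read_labels()`: named character vector of labels.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("area_id", "label") %in% names(df)))
    stop("label CSV needs area_id and label columns", call. = FALSE)
  stats::setNames(as.character(df$label), df$area_id)
}

#' @rdname read_labels
#' @param labels named vector of labels (names = area ids).
#' @export
write_labels <- function(labels, path) {
  utils::write.csv(data.frame(area_id = names(labels),
                              label = unname(labels)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Save a fitted model as a JSON document
#'
#' Serialises the parameter set, fit statistics and convergence metadata
#' (not the data or posteriors; those travel as CSV via [write_labels()]).
#' @param model a [gbmt()] fit.
#' @param path output path.
#' @export
write_gbmt_json <- function(model, path) {
  stopifnot(inherits(model, "gbmt"))
  doc <- list(groups = model$groups, family = model$family,
              variance = model$variance, pi = model$pi,
              orders = model$orders, beta = model$beta,
              sigma = model$sigma, logL = model$logL,
              n_params = model$n_params, n_obs = model$n_obs,
              converged = model$converged, n_iter = model$n_iter,
              seed = model$seed)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run the full classification pipeline
#'
#' Executes the end-to-end workflow from a configuration list or YAML file:
#' read counts (or a ready panel), optionally convert boundaries, build
#' indicators, enumerate candidate models over a range of group counts,
#' adjust polynomial orders of the preferred model, classify areas, profile
#' clusters against an optional attribute table, and optionally compare the
#' classification with an external label table. Artifacts (enumeration
#' table, model JSON, label CSV, profile CSV, association summary, run log
#' with seed and config hash) are written to `output_dir`.
#'
#' Config fields: one of `counts_csv` or `panel_csv`; optional
#' `lookup_csv`; `G_range` (default `2:7`); `orders`, `variance`,
#' `n_starts`, `seed`, `alpha` (order-adjustment level; `NULL` skips
#' adjustment); optional `attributes_csv`, `compare_labels_csv`;
#' `output_dir`.
#'
#' @param config named list, or path to a YAML file with these fields.
#' @return Invisibly, a list with the fitted `model`, `enumeration`,
#'   `labels`, `profile`, `association`, and `paths` of written artifacts.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("no such config: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(
    list(G_range = 2:7, orders = NULL, variance = "shared",
         n_starts = 3L, seed = 1L, alpha = 0.05, output_dir = "."),
    config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  panel <- if (!is.null(cfg$panel_csv)) {
    stage("read_panel", read_panel(cfg$panel_csv))
  } else if (!is.null(cfg$counts_csv)) {
    counts <- stage("read_counts", {
      if (!file.exists(cfg$counts_csv))
        stop("no such file: ", cfg$counts_csv)
      utils::read.csv(cfg$counts_csv, stringsAsFactors = FALSE)
    })
    if (!is.null(cfg$lookup_csv)) {
      lookup <- stage("read_lookup", read_lookup(cfg$lookup_csv))
      counts <- stage("convert", {
        by_year <- split(counts, counts$year)
        out <- lapply(names(by_year), function(y) {
          d <- by_year[[y]]
          conv <- convert_counts(
            cbind(data.frame(area_id = d$area_id),
                  d[setdiff(names(d), c("area_id", "year"))]), lookup)
          conv$year <- as.numeric(y)
          conv
        })
        do.call(rbind, out)
      })
    }
    stage("indicators", build_panel(counts))
  } else stop("config needs 'counts_csv' or 'panel_csv'", call. = FALSE)

  enum <- stage("enumerate",
                gbmt_enumerate(panel, cfg$G_range, orders = cfg$orders,
                               variance = cfg$variance,
                               n_starts = cfg$n_starts, seed = cfg$seed))
  G_best <- enum$best_bic_obs
  model <- enum$models[[paste0("G", G_best)]]
  if (!is.null(cfg$alpha))
    model <- stage("adjust", adjust_orders(model, alpha = cfg$alpha))
  labels <- stats::setNames(as.character(model$labels), panel$areas)

  profile <- NULL
  if (!is.null(cfg$attributes_csv)) {
    attrs <- stage("read_attributes",
                   utils::read.csv(cfg$attributes_csv,
                                   stringsAsFactors = FALSE))
    attrs <- attrs[match(panel$areas, attrs$area_id), , drop = FALSE]
    profile <- stage("profile", cluster_profile(model$labels, attrs))
  }
  assoc <- NULL
  if (!is.null(cfg$compare_labels_csv)) {
    ext <- stage("read_compare_labels", read_labels(cfg$compare_labels_csv))
    assoc <- stage("compare",
                   classification_association(labels[panel$areas],
                                              ext[panel$areas]))
  }

  paths <- list(
    enumeration = file.path(cfg$output_dir, "enumeration.csv"),
    model = file.path(cfg$output_dir, "model.json"),
    labels = file.path(cfg$output_dir, "labels.csv"),
    log = file.path(cfg$output_dir, "run_log.txt"))
  utils::write.csv(enum$table, paths$enumeration, row.names = FALSE)
  write_gbmt_json(model, paths$model)
  write_labels(labels, paths$labels)
  if (!is.null(profile)) {
    paths$profile <- file.path(cfg$output_dir, "profile.csv")
    utils::write.csv(as.data.frame(profile$means), paths$profile)
  }
  if (!is.null(assoc)) {
    paths$association <- file.path(cfg$output_dir, "association.json")
    jsonlite::write_json(
      list(chi2 = assoc$chi2, df = assoc$df, p = assoc$p,
           cramers_v = assoc$cramers_v, n = assoc$n),
      paths$association, auto_unbox = TRUE, digits = NA)
  }
  writeLines(c(
    sprintf("migtraj run %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    sprintf("seed: %d", cfg$seed),
    sprintf("config_hash: %s", config_hash(cfg)),
    sprintf("selected_G: %d", G_best),
    sprintf("R: %s", R.version.string)), paths$log)
  invisible(list(model = model, enumeration = enum, labels = labels,
                 profile = profile, association = assoc, paths = paths))
}

# stable md5 of the deparsed config (timestamp-free)
config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(cfg[order(names(cfg))]), tmp)
  unname(tools::md5sum(tmp))
}
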