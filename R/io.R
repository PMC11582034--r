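#' Read a run configuration (YAML or JSON)
#'
#' The configuration declares each data column's role and unit label plus
#' solver and reporting settings. Recognized top-level keys:
#' \describe{
#'   \item{variables}{mapping column name -> `{role, unit_label}`; roles as
#'     in [rdm_schema()].}
#'   \item{solver}{optional: `lp_eps`, `efficiency_tol`, `reference_tol`.}
#'   \item{era_threshold_year}{optional, default 2010.}
#'   \item{reference_threshold}{optional reporting threshold, default 0.01.}
#'   \item{seed}{optional integer used by `simulate`.}
#' }
#'
#' @param path Path to a YAML (or JSON, a YAML subset) file.
#' @return A list of class `rdm_config` with elements `schema`, `control`,
#'   `era_threshold_year`, `reference_threshold`, `seed`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$variables) || !length(raw$variables)) {
    stop("config must declare a `variables` mapping", call. = FALSE)
  }
  vars <- raw$variables
  roles <- vapply(vars, function(v) {
    if (is.null(v$role)) stop("every variable needs a `role`", call. = FALSE)
    v$role
  }, character(1))
  labels <- vapply(vars, function(v)
    if (is.null(v$unit_label)) "" else v$unit_label, character(1))
  schema <- rdm_schema(names(vars), unname(roles), unname(labels))
  sv <- if (is.null(raw$solver)) list() else raw$solver
  control <- rdm_control(
    lp_eps = sv$lp_eps %||% 1e-10,
    efficiency_tol = sv$efficiency_tol %||% 1e-7,
    reference_tol = sv$reference_tol %||% 1e-6
  )
  ref_thr <- raw$reference_threshold %||% 0.01
  if (ref_thr <= 0 || ref_thr >= 1) {
    stop("`reference_threshold` must lie in (0, 1)", call. = FALSE)
  }
  structure(list(
    schema = schema,
    control = control,
    era_threshold_year = as.integer(raw$era_threshold_year %||% 2010L),
    reference_threshold = ref_thr,
    seed = raw$seed
  ), class = "rdm_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a panel from CSV under a declared schema
#'
#' Expects an RFC 4180 CSV with a header row: column `id`, optional `class`
#' and `approval_year`, and exactly the variable columns declared in the
#' configuration. Validation is strict — unknown columns, missing values
#' and non-positive inputs are errors that cite the offending rows; no
#' imputation and no silent sign flipping. Zeros in output columns (the
#' convention for label text reporting "no significant change") are
#' accepted and noted.
#'
#' @param csv_path Path to the panel CSV.
#' @param config An [read_run_config()] result (or an [rdm_schema()], used
#'   directly).
#' @return An [rdm_panel()].
#' @examples
#' cfg <- read_run_config(system.file("extdata", "example_config.yaml",
#'                                    package = "rdmdea"))
#' pan <- read_panel(system.file("extdata", "example_panel_synthetic.csv",
#'                               package = "rdmdea"), cfg)
#' as.data.frame(evaluate_all(pan))
#' @export
read_panel <- function(csv_path, config) {
  if (!file.exists(csv_path)) {
    stop("panel file not found: ", csv_path, call. = FALSE)
  }
  schema <- if (inherits(config, "rdm_schema")) config else config$schema
  stopifnot(inherits(schema, "rdm_schema"))
  tab <- utils::read.csv(csv_path, stringsAsFactors = FALSE,
                         check.names = FALSE, fileEncoding = "UTF-8")
  panel <- rdm_panel(tab, schema)
  out_vars <- schema_vars(panel$schema, "desirable_output")
  for (v in out_vars) {
    nz <- sum(panel$data[[v]] == 0)
    if (nz > 0) {
      message("note: ", nz, " zero value(s) in `", v,
              "` ingested as reported zeros (\"no significant change\")")
    }
  }
  panel
}

#' Write the full result bundle as CSV files
#'
#' Emits four deterministic files into `out_dir`:
#' `results.csv` (per unit: `id`, `theta_star`, `efficiency`, `rank`,
#' `references` as `ref_id:weight` pairs, full precision),
#' `ranking.csv` (rank table, efficiency at 3 decimals for presentation),
#' `slacks.csv` (one row per unit and variable: raw and normalized slack),
#' and `era.csv` (era comparison). Row and column order are fixed, so
#' reruns on identical inputs are byte-identical.
#'
#' @param results An [evaluate_all()] result set.
#' @param ranking A [rank_units()] table.
#' @param slacks A list of [compute_slacks()] reports (possibly empty).
#' @param era An [era_compare()] result, or `NULL` to skip `era.csv`.
#' @param out_dir Output directory, created if missing.
#' @param reference_threshold Weights below this are dropped from the
#'   `references` column.
#' @return Invisibly, the named character vector of file paths written.
#' @export
write_results <- function(results, ranking, slacks, era, out_dir,
                          reference_threshold = 0.01) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir)) {
      stop("cannot create output directory: ", out_dir, call. = FALSE)
    }
  }
  stopifnot(inherits(results, "rdm_result_set"))
  fmt <- function(x) formatC(x, format = "g", digits = 17)

  res_tab <- as.data.frame(results)
  rk <- ranking[, c("id", "rank")]
  res_tab <- merge(res_tab, rk, by = "id", sort = FALSE)
  res_tab$references <- vapply(res_tab$id, function(id) {
    r <- results[[id]]
    if (is.null(r$lambda)) return("")
    w <- r$lambda[r$lambda > reference_threshold]
    if (!length(w)) w <- r$lambda[which.max(r$lambda)]  # always >= 1/n
    w <- sort(w / sum(w), decreasing = TRUE)
    paste(sprintf("%s:%s", names(w), fmt(w)), collapse = ";")
  }, character(1))
  res_tab <- res_tab[order(res_tab$id),
                     c("id", "theta_star", "efficiency", "rank", "references")]
  res_tab$theta_star <- fmt(res_tab$theta_star)
  res_tab$efficiency <- fmt(res_tab$efficiency)

  paths <- c(results = file.path(out_dir, "results.csv"),
             ranking = file.path(out_dir, "ranking.csv"),
             slacks = file.path(out_dir, "slacks.csv"))
  utils::write.csv(res_tab, paths[["results"]], row.names = FALSE)

  rk_out <- as.data.frame(ranking)
  rk_out$efficiency <- sprintf("%.3f", rk_out$efficiency)
  utils::write.csv(rk_out, paths[["ranking"]], row.names = FALSE)

  if (length(slacks)) {
    sl <- do.call(rbind, lapply(slacks, function(s) {
      data.frame(id = s$unit_id, variable = names(s$raw),
                 raw_slack = unname(s$raw),
                 normalized_slack = unname(s$normalized),
                 stringsAsFactors = FALSE)
    }))
    sl <- sl[order(sl$id, sl$variable), ]
    sl$raw_slack <- fmt(sl$raw_slack)
    sl$normalized_slack <- fmt(sl$normalized_slack)
  } else {
    sl <- data.frame(id = character(0), variable = character(0),
                     raw_slack = character(0), normalized_slack = character(0))
  }
  utils::write.csv(sl, paths[["slacks"]], row.names = FALSE)

  if (!is.null(era)) {
    paths <- c(paths, era = file.path(out_dir, "era.csv"))
    era_tab <- data.frame(threshold_year = era$threshold_year,
                          pre_mean = fmt(era$pre_mean),
                          post_mean = fmt(era$post_mean),
                          pre_count = era$pre_count,
                          post_count = era$post_count,
                          inclusive_post = era$inclusive_post)
    utils::write.csv(era_tab, paths[["era"]], row.names = FALSE)
  }
  invisible(paths)
}

#' Run the complete benchmarking pipeline on a panel
#'
#' Scores every unit, computes phase-II slacks, ranks, compares eras (when
#' approval years are available) and optionally writes the CSV bundle.
#'
#' @inheritParams solve_rdm
#' @param era_threshold_year Split year for the era comparison.
#' @param reference_threshold Reporting threshold for reference weights.
#' @param out_dir If non-`NULL`, results are written there via
#'   [write_results()].
#' @return A list with `results`, `slacks`, `ranking`, `era` (or `NULL`),
#'   `timeline` (or `NULL`), `slack_summary`, and `paths` when files were
#'   written.
#' @export
run_pipeline <- function(panel, control = rdm_control(),
                         era_threshold_year = 2010,
                         reference_threshold = 0.01,
                         out_dir = NULL) {
  stopifnot(inherits(panel, "rdm_panel"))
  results <- evaluate_all(panel, control)
  slacks <- lapply(unit_ids(panel), function(id)
    compute_slacks(panel, id, results[[id]], control))
  names(slacks) <- unit_ids(panel)
  ranking <- rank_units(results, panel)
  has_years <- "approval_year" %in% names(panel$data) &&
    any(!is.na(panel$data$approval_year))
  era <- if (has_years)
    era_compare(results, panel, era_threshold_year) else NULL
  timeline <- if (has_years) efficiency_timeline(results, panel) else NULL
  paths <- NULL
  if (!is.null(out_dir)) {
    paths <- write_results(results, ranking, slacks, era, out_dir,
                           reference_threshold)
  }
  list(results = results, slacks = slacks, ranking = ranking, era = era,
       timeline = timeline, slack_summary = slack_summary(slacks),
       paths = paths)
}
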