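#' Rank units by efficiency with competition ranking
#'
#' Orders units from most to least efficient. Ties share the minimal rank
#' and the next distinct efficiency skips accordingly (1224 ranking, the
#' pattern "7, 7, 9" seen in published efficiency tables). Row order among
#' tied units is lexicographic by id; ranking uses full-precision
#' efficiencies, rounding is left to the presentation layer.
#'
#' @param results An [evaluate_all()] result set (or a data frame with
#'   columns `id` and `efficiency`).
#' @param panel Optional [rdm_panel()]; when given, `approval_year` and
#'   `class` metadata are joined onto the table.
#' @return A data frame of class `rdm_ranking` with columns `rank`, `id`,
#'   (`class`, `approval_year` if available) and `efficiency`, sorted by
#'   efficiency descending.
#' @examples
#' tab <- data.frame(id = c("a", "b", "c", "d"),
#'                   efficiency = c(0.857, 0.564, 0.564, 0.553))
#' rank_units(tab)  # ranks 1, 2, 2, 4
#' @export
rank_units <- function(results, panel = NULL) {
  tab <- results_table(results)
  if (anyDuplicated(tab$id)) {
    stop("duplicate unit ids in results", call. = FALSE)
  }
  tab <- tab[order(-tab$efficiency, tab$id), , drop = FALSE]
  # competition ranking ("min" ties method on the descending sort)
  tab$rank <- rank(-tab$efficiency, ties.method = "min")
  if (!is.null(panel)) {
    stopifnot(inherits(panel, "rdm_panel"))
    meta <- panel$data[, intersect(c("id", "class", "approval_year"),
                                   names(panel$data)), drop = FALSE]
    tab <- merge(tab, meta, by = "id", sort = FALSE)
    tab <- tab[order(tab$rank, tab$id), , drop = FALSE]
  }
  front <- intersect(c("rank", "id", "class", "approval_year", "efficiency"),
                     names(tab))
  tab <- tab[, c(front, setdiff(names(tab), front)), drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("rdm_ranking", "data.frame")
  tab
}

results_table <- function(results) {
  if (inherits(results, "rdm_result_set")) {
    as.data.frame(results)
  } else {
    tab <- as.data.frame(results)
    stopifnot(all(c("id", "efficiency") %in% names(tab)))
    tab
  }
}

#' Compare mean efficiency across approval eras
#'
#' Splits units at a threshold approval year (default 2010, post era
#' inclusive of the threshold year) and reports the arithmetic mean
#' efficiency and unit count on each side — the technological-progress
#' contrast between older and newer drug generations. Units without an
#' approval year are excluded with a warning. An empty era yields an `NA`
#' mean (never zero) with counts intact.
#'
#' @inheritParams rank_units
#' @param panel An [rdm_panel()] carrying `approval_year` metadata.
#' @param threshold_year Integer split year; units with
#'   `approval_year >= threshold_year` form the post era.
#' @return A list of class `rdm_era` with `threshold_year`, `pre_mean`,
#'   `post_mean`, `pre_count`, `post_count`, `inclusive_post = TRUE`, and
#'   `excluded` (ids lacking a year).
#' @export
era_compare <- function(results, panel, threshold_year = 2010) {
  stopifnot(inherits(panel, "rdm_panel"))
  tab <- results_table(results)
  if (!"approval_year" %in% names(panel$data)) {
    stop("panel has no `approval_year` column", call. = FALSE)
  }
  tab <- merge(tab, panel$data[, c("id", "approval_year")], by = "id")
  excluded <- tab$id[is.na(tab$approval_year)]
  if (length(excluded)) {
    warning("excluding ", length(excluded), " unit(s) without approval year: ",
            paste(excluded, collapse = ", "), call. = FALSE)
  }
  tab <- tab[!is.na(tab$approval_year), , drop = FALSE]
  if (!nrow(tab)) stop("no unit carries an approval year", call. = FALSE)
  post <- tab$approval_year >= threshold_year
  mean_or_na <- function(x) if (length(x)) mean(x) else NA_real_
  structure(list(
    threshold_year = as.integer(threshold_year),
    pre_mean = mean_or_na(tab$efficiency[!post]),
    post_mean = mean_or_na(tab$efficiency[post]),
    pre_count = sum(!post),
    post_count = sum(post),
    inclusive_post = TRUE,
    excluded = as.character(excluded)
  ), class = "rdm_era")
}

#' @export
print.rdm_era <- function(x, ...) {
  cat("<rdm_era> split at ", x$threshold_year, " (post era inclusive)\n",
      sprintf("  pre : mean efficiency %s over %d unit(s)\n",
              format(x$pre_mean, digits = 4), x$pre_count),
      sprintf("  post: mean efficiency %s over %d unit(s)\n",
              format(x$post_mean, digits = 4), x$post_count), sep = "")
  invisible(x)
}

#' Tally which variable drives inefficiency across a panel
#'
#' Counts, over the inefficient units, how often each variable carries the
#' largest normalized slack (e.g. "for 8 of 20 drugs the biggest slack was
#' dose frequency"). Units whose slacks are all zero (frontier projections)
#' are excluded.
#'
#' @param slack_reports A list of [compute_slacks()] results computed on a
#'   common panel.
#' @return A named integer vector of class `rdm_slack_summary` mapping
#'   variable name to count; sums to the number of units with a nonzero
#'   slack.
#' @export
slack_summary <- function(slack_reports) {
  stopifnot(is.list(slack_reports),
            all(vapply(slack_reports, inherits, logical(1), "rdm_slacks")))
  largest <- vapply(slack_reports, `[[`, character(1), "largest")
  largest <- largest[!is.na(largest)]
  counts <- table(largest)
  out <- stats::setNames(as.integer(counts), names(counts))
  out <- sort(out, decreasing = TRUE)
  class(out) <- c("rdm_slack_summary", class(out))
  out
}

#' Efficiency by approval year
#'
#' Arranges per-unit efficiencies as a time series ordered by approval year
#' (ties by id), ready for plotting the technological-progress trajectory.
#' Units without an approval year are dropped with a warning. No
#' aggregation is applied.
#'
#' @inheritParams era_compare
#' @return A data frame with columns `approval_year`, `id`, `efficiency`.
#' @export
efficiency_timeline <- function(results, panel) {
  stopifnot(inherits(panel, "rdm_panel"))
  tab <- results_table(results)
  if (!"approval_year" %in% names(panel$data)) {
    stop("panel has no `approval_year` column", call. = FALSE)
  }
  tab <- merge(tab, panel$data[, c("id", "approval_year")], by = "id")
  dropped <- tab$id[is.na(tab$approval_year)]
  if (length(dropped)) {
    warning("excluding ", length(dropped), " unit(s) without approval year: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  tab <- tab[!is.na(tab$approval_year), , drop = FALSE]
  tab <- tab[order(tab$approval_year, tab$id),
             c("approval_year", "id", "efficiency"), drop = FALSE]
  rownames(tab) <- NULL
  tab
}
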