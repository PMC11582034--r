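#' Declare the variable schema of a benchmark panel
#'
#' A schema assigns each variable column a role in the envelopment model:
#' `"input"` (less is better, strictly positive, e.g. dose frequency per day),
#' `"desirable_output"` (more is better, any sign, e.g. HbA1c reduction in
#' percentage points, weight change with loss coded positive) or
#' `"undesirable_output"` (less is better, any sign, e.g. all-cause mortality
#' odds ratio against placebo). Undesirable outputs enter the model like
#' inputs, through their own improvement range.
#'
#' @param name Character vector of variable names (unique).
#' @param role Character vector of roles, one per variable; each must be one
#'   of `"input"`, `"desirable_output"`, `"undesirable_output"`.
#' @param unit_label Optional character vector of unit labels (e.g.
#'   `"per day"`, `"%"`); defaults to empty strings.
#' @return An object of class `rdm_schema`: a data frame with columns
#'   `name`, `role`, `unit_label`.
#' @examples
#' rdm_schema(
#'   name = c("dose_frequency", "hba1c_reduction", "weight_change"),
#'   role = c("input", "desirable_output", "desirable_output"),
#'   unit_label = c("per day", "%", "%")
#' )
#' @export
rdm_schema <- function(name, role, unit_label = NULL) {
  name <- as.character(name)
  role <- as.character(role)
  if (length(name) != length(role)) {
    stop("`name` and `role` must have the same length", call. = FALSE)
  }
  if (anyDuplicated(name)) {
    stop("variable names must be unique: ",
         paste(unique(name[duplicated(name)]), collapse = ", "), call. = FALSE)
  }
  valid <- c("input", "desirable_output", "undesirable_output")
  bad <- setdiff(role, valid)
  if (length(bad)) {
    stop("invalid role(s): ", paste(bad, collapse = ", "),
         "; must be one of ", paste(valid, collapse = ", "), call. = FALSE)
  }
  if (!any(role == "input")) {
    stop("schema needs at least one input variable", call. = FALSE)
  }
  if (!any(role %in% c("desirable_output", "undesirable_output"))) {
    stop("schema needs at least one output variable", call. = FALSE)
  }
  if (is.null(unit_label)) unit_label <- rep("", length(name))
  unit_label <- as.character(unit_label)
  if (length(unit_label) != length(name)) {
    stop("`unit_label` must match `name` in length", call. = FALSE)
  }
  out <- data.frame(name = name, role = role, unit_label = unit_label,
                    stringsAsFactors = FALSE)
  class(out) <- c("rdm_schema", "data.frame")
  out
}

schema_vars <- function(schema, role = NULL) {
  if (is.null(role)) schema$name else schema$name[schema$role == role]
}

#' Assemble a benchmark panel of decision-making units
#'
#' Binds a table of units (one row per drug) to a variable schema and
#' validates the model's domain requirements: at least two units, unique ids,
#' no missing values, and strictly positive inputs. Desirable and undesirable
#' outputs may take any sign; sign conventions (e.g. weight loss positive,
#' gain negative) are the caller's responsibility and are never flipped here.
#'
#' @param data A data frame with an `id` column, optional `class` and
#'   `approval_year` columns, and one numeric column per schema variable.
#'   No other columns are allowed.
#' @param schema An [rdm_schema()].
#' @return An object of class `rdm_panel`: a list with elements `schema`,
#'   `data` (the validated unit table) and cached role matrices.
#' @examples
#' sch <- rdm_schema(c("x", "y"), c("input", "desirable_output"))
#' pan <- rdm_panel(data.frame(id = c("A", "B", "C"),
#'                             x = c(1, 2, 2), y = c(2, 4, 2)), sch)
#' pan
#' @export
rdm_panel <- function(data, schema) {
  stopifnot(inherits(schema, "rdm_schema"))
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  if (!"id" %in% names(data)) stop("`data` must have an `id` column", call. = FALSE)
  meta_cols <- intersect(c("id", "class", "approval_year"), names(data))
  extra <- setdiff(names(data), c(meta_cols, schema$name))
  if (length(extra)) {
    stop("unknown column(s) not in schema: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  missing_vars <- setdiff(schema$name, names(data))
  if (length(missing_vars)) {
    stop("schema variable(s) missing from data: ",
         paste(missing_vars, collapse = ", "), call. = FALSE)
  }
  if (nrow(data) < 2) stop("a panel needs at least 2 units", call. = FALSE)
  data$id <- as.character(data$id)
  if (anyDuplicated(data$id)) {
    stop("unit ids must be unique: ",
         paste(unique(data$id[duplicated(data$id)]), collapse = ", "),
         call. = FALSE)
  }
  for (v in schema$name) {
    col <- data[[v]]
    if (!is.numeric(col)) stop("variable `", v, "` must be numeric", call. = FALSE)
    if (anyNA(col)) {
      stop("variable `", v, "` has missing values for unit(s): ",
           paste(data$id[is.na(col)], collapse = ", "), call. = FALSE)
    }
  }
  inp <- schema_vars(schema, "input")
  for (v in inp) {
    bad <- data$id[data[[v]] <= 0]
    if (length(bad)) {
      stop("input `", v, "` must be strictly positive; violated by unit(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  if ("approval_year" %in% names(data) && !all(is.na(data$approval_year))) {
    yr <- data$approval_year
    if (!is.numeric(yr)) stop("`approval_year` must be numeric", call. = FALSE)
    if (any(!is.na(yr) & yr != round(yr))) {
      stop("`approval_year` must be whole years", call. = FALSE)
    }
  }
  role_matrix <- function(role) {
    vars <- schema_vars(schema, role)
    m <- as.matrix(data[, vars, drop = FALSE])
    rownames(m) <- data$id
    m
  }
  structure(list(
    schema = schema,
    data = data,
    X = role_matrix("input"),
    Y = role_matrix("desirable_output"),
    Z = role_matrix("undesirable_output")
  ), class = "rdm_panel")
}

n_units <- function(panel) nrow(panel$data)

unit_ids <- function(panel) panel$data$id

# Resolve a unit id (or 1-based index) to its row index, erroring on unknowns.
unit_index <- function(panel, o) {
  if (is.numeric(o)) {
    o <- as.integer(o)
    if (o < 1L || o > n_units(panel)) {
      stop("unit index out of range: ", o, call. = FALSE)
    }
    return(o)
  }
  i <- match(as.character(o), unit_ids(panel))
  if (is.na(i)) stop("unknown unit id: ", o, call. = FALSE)
  i
}

#' @export
print.rdm_schema <- function(x, ...) {
  cat("<rdm_schema> ", nrow(x), " variable(s)\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' @export
print.rdm_panel <- function(x, ...) {
  cat("<rdm_panel> ", n_units(x), " units, ",
      ncol(x$X), " input(s), ", ncol(x$Y), " desirable output(s), ",
      ncol(x$Z), " undesirable output(s)\n", sep = "")
  print(utils::head(x$data, 10), row.names = FALSE)
  if (n_units(x) > 10) cat("... and", n_units(x) - 10, "more units\n")
  invisible(x)
}

#' @export
as.data.frame.rdm_panel <- function(x, ...) x$data
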