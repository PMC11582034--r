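#' Parameters of one synthetic drug class
#'
#' Describes the class-level structure from which synthetic drug profiles
#' are drawn: a finite support of dosing frequencies (per day; weekly dosing
#' is 1/7), a truncated-normal HbA1c reduction (strictly positive, %), a
#' normal weight change (%, loss positive — classes with a negative mean
#' produce weight-gain drugs), and a log-normal all-cause mortality odds
#' ratio.
#'
#' @param class_name Class label, e.g. `"GLP-1 analogs"`.
#' @param dose_frequency_support Finite set of strictly positive per-day
#'   dose frequencies sampled uniformly.
#' @param hba1c_mean,hba1c_sd Mean and sd of HbA1c reduction (%); draws are
#'   truncated to be strictly positive.
#' @param weight_mean,weight_sd Mean and sd of weight change (%); negative
#'   draws (weight gain) are allowed and expected for some classes.
#' @param mortality_log_or_mean,mortality_log_or_sd Mean and sd of the log
#'   odds ratio of all-cause mortality versus placebo; the OR itself is
#'   `exp` of a normal draw, hence always positive.
#' @param units_per_class Number of drugs to draw for this class.
#' @param year_range Integer vector of length 2; approval years are drawn
#'   uniformly from this range.
#' @return A list of class `rdm_class_params`.
#' @export
class_params <- function(class_name, dose_frequency_support,
                         hba1c_mean, hba1c_sd,
                         weight_mean, weight_sd,
                         mortality_log_or_mean = 0,
                         mortality_log_or_sd = 0.1,
                         units_per_class = 1L,
                         year_range = c(1995L, 2023L)) {
  stopifnot(length(class_name) == 1, length(dose_frequency_support) >= 1,
            all(dose_frequency_support > 0),
            hba1c_sd >= 0, weight_sd >= 0, mortality_log_or_sd >= 0,
            hba1c_mean > 0,
            units_per_class >= 1, length(year_range) == 2,
            year_range[1] <= year_range[2])
  structure(list(class_name = as.character(class_name),
                 dose_frequency_support = as.numeric(dose_frequency_support),
                 hba1c_mean = hba1c_mean, hba1c_sd = hba1c_sd,
                 weight_mean = weight_mean, weight_sd = weight_sd,
                 mortality_log_or_mean = mortality_log_or_mean,
                 mortality_log_or_sd = mortality_log_or_sd,
                 units_per_class = as.integer(units_per_class),
                 year_range = as.integer(year_range)),
            class = "rdm_class_params")
}

#' Default synthetic class parameters for T2D drug panels
#'
#' Class-level dose-frequency supports, HbA1c means/sds and weight-change
#' means/sds transcribed from published class summaries of FDA-labelled T2D
#' drugs (e.g. Glinides with mean weight change −2.815%, GLP-1 analogs with
#' dose frequencies down to 0.14/day, i.e. weekly). Mortality log-OR
#' parameters are this package's own plausible choices (modestly protective
#' for GLP-1 and SGLT2 classes, near-null elsewhere), since class-level
#' mortality summaries are not published alongside the label data. Approval
#' year ranges reflect each class's era of FDA approvals.
#'
#' @return A list of [class_params()] objects, one per drug class.
#' @export
default_class_params <- function() {
  list(
    class_params("Sulfonylureas", 1, 1.700, 0, 0.000, 0,
                 0.05, 0.05, 1L, c(1984L, 1994L)),
    class_params("Biguanides", c(1, 2), 1.068, 0.452, 0.000, 0.304,
                 -0.05, 0.05, 5L, c(1994L, 2005L)),
    class_params("Glinides", c(2, 3), 0.450, 0.005, -2.815, 0.470,
                 0.02, 0.05, 2L, c(1997L, 2000L)),
    class_params("Thiazolidinediones", 1, 0.800, 0, -2.200, 0,
                 0.05, 0.05, 1L, c(1999L, 1999L)),
    class_params("GLP-1 analogs", c(1 / 7, 1, 2), 0.884, 0.098, 2.344, 5.378,
                 -0.15, 0.08, 7L, c(2005L, 2023L)),
    class_params("SGLT2 inhibitors", 1, 0.642, 0.044, 2.338, 0.463,
                 -0.15, 0.08, 5L, c(2013L, 2023L)),
    class_params("DPP-4 inhibitors", 1, 0.667, 0.013, 0.000, 0,
                 0.00, 0.05, 3L, c(2006L, 2013L)),
    class_params("Dopamine D2 receptors", 1, 0.400, 0, -0.340, 0,
                 0.02, 0.05, 1L, c(2009L, 2009L)),
    class_params("Combination oral pills", c(1, 2), 0.884, 0.170, 0.489, 1.943,
                 0.00, 0.05, 13L, c(2000L, 2020L))
  )
}

rtruncnorm_pos <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {                       # rejection sampling, > 0
    draw <- stats::rnorm(length(todo), mean, sd)
    ok <- draw > 0
    out[todo[ok]] <- draw[ok]
    todo <- todo[!ok]
  }
  out
}

#' Generate a synthetic drug-profile panel
#'
#' Draws one panel of synthetic drugs from class-level parameters:
#' dose frequency uniformly from the class support, HbA1c reduction from a
#' positive-truncated normal, weight change from a normal (negative values
#' — weight gain — arise whenever the class mean allows), mortality OR as
#' the exponential of a normal log-OR, and approval year uniformly over the
#' class's era. Deterministic for a fixed seed.
#'
#' @param params A list of [class_params()] (default
#'   [default_class_params()]).
#' @param seed Integer seed; required for reproducibility.
#' @param include_mortality Include the mortality undesirable output
#'   (compound-level configuration)? If `FALSE` the panel has the
#'   branded-level configuration (dose in, HbA1c and weight out).
#' @return An [rdm_panel()] whose schema follows the chosen configuration.
#' @examples
#' pan <- generate_panel(seed = 42)
#' pan
#' @export
generate_panel <- function(params = default_class_params(), seed,
                           include_mortality = TRUE) {
  if (!is.list(params) || !length(params)) {
    stop("`params` must be a non-empty list of class_params", call. = FALSE)
  }
  stopifnot(all(vapply(params, inherits, logical(1), "rdm_class_params")))
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  set.seed(as.integer(seed))
  rows <- lapply(params, function(p) {
    k <- p$units_per_class
    data.frame(
      id = sprintf("%s_%02d", gsub("[^A-Za-z0-9]+", "_", p$class_name),
                   seq_len(k)),
      class = p$class_name,
      approval_year = sample(seq(p$year_range[1], p$year_range[2]), k,
                             replace = TRUE),
      dose_frequency = sample(p$dose_frequency_support, k, replace = TRUE),
      hba1c_reduction = rtruncnorm_pos(k, p$hba1c_mean, p$hba1c_sd),
      weight_change = stats::rnorm(k, p$weight_mean, p$weight_sd),
      mortality_or = exp(stats::rnorm(k, p$mortality_log_or_mean,
                                      p$mortality_log_or_sd)),
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, rows)
  if (include_mortality) {
    schema <- rdm_schema(
      c("dose_frequency", "hba1c_reduction", "weight_change", "mortality_or"),
      c("input", "desirable_output", "desirable_output", "undesirable_output"),
      c("per day", "%", "%", "odds ratio"))
  } else {
    schema <- rdm_schema(
      c("dose_frequency", "hba1c_reduction", "weight_change"),
      c("input", "desirable_output", "desirable_output"),
      c("per day", "%", "%"))
    tab$mortality_or <- NULL
  }
  rdm_panel(tab, schema)
}

#' Plant a unit with a prescribed inefficiency score
#'
#' Given an anchor point on the frontier and a target score
#' \eqn{\theta \in [0, 1)}, constructs the unit that the range directional
#' move by \eqn{\theta} carries exactly onto the anchor: per input or
#' undesirable output, \eqn{v_o = (p - \theta\,\mathrm{min})/(1 - \theta)};
#' per desirable output, \eqn{v_o = (p - \theta\,\mathrm{max})/(1 - \theta)}
#' (min/max over the panel). The construction is rejected if the planted
#' unit would create a new panel extreme for any range-defining variable,
#' since that would change every unit's improvement ranges.
#'
#' @param panel An [rdm_panel()] whose extreme points must stay extreme.
#' @param anchor_point Named numeric vector over the schema variables; a
#'   point on (ideally in the interior of a facet of) the frontier.
#' @param theta Target inefficiency score in `[0, 1)`.
#' @param id Id for the planted unit.
#' @return A one-row data frame with the planted unit's values.
#' @export
plant_inefficient_unit <- function(panel, anchor_point, theta,
                                   id = "planted") {
  stopifnot(inherits(panel, "rdm_panel"))
  if (!is.numeric(theta) || length(theta) != 1 || theta < 0 || theta >= 1) {
    stop("`theta` must lie in [0, 1)", call. = FALSE)
  }
  sch <- panel$schema
  if (!all(sch$name %in% names(anchor_point))) {
    stop("`anchor_point` must name every schema variable", call. = FALSE)
  }
  vals <- stats::setNames(numeric(nrow(sch)), sch$name)
  for (v in sch$name) {
    col <- panel$data[[v]]
    p <- anchor_point[[v]]
    if (sch$role[sch$name == v] == "desirable_output") {
      ext <- max(col)
      vals[v] <- (p - theta * ext) / (1 - theta)
      if (vals[v] > ext + 1e-12) {
        stop("planting would raise the panel maximum of `", v, "`",
             call. = FALSE)
      }
    } else {
      ext <- min(col)
      vals[v] <- (p - theta * ext) / (1 - theta)
      if (vals[v] < ext - 1e-12) {
        stop("planting would lower the panel minimum of `", v, "`",
             call. = FALSE)
      }
      if (sch$role[sch$name == v] == "input" && vals[v] <= 0) {
        stop("planted input `", v, "` is not strictly positive", call. = FALSE)
      }
    }
  }
  out <- data.frame(id = id, stringsAsFactors = FALSE)
  for (v in sch$name) out[[v]] <- vals[[v]]
  out
}

# Frontier anchors on a strictly concave curve y = a * sqrt(x): consecutive
# vertices are mutually non-dominated and every inter-vertex facet lies on
# the VRS frontier, so facet-interior anchors are easy to construct.
concave_frontier <- function(n_frontier, seed_offset = 0) {
  x <- seq(1, 4, length.out = n_frontier)
  data.frame(id = sprintf("frontier_%02d", seq_len(n_frontier)),
             x = x, y = 4 * sqrt(x), stringsAsFactors = FALSE)
}

#' Build a panel with known (planted) inefficiency scores
#'
#' Constructs a two-variable panel (one input, one desirable output) whose
#' frontier is a strictly concave polyline of `n_frontier` vertices, then
#' plants one unit per requested score at a uniformly drawn facet-interior
#' anchor via [plant_inefficient_unit()]. Solving the panel recovers each
#' planted score: along the unit's own range direction the concave envelope
#' is crossed exactly at the anchor. Frontier vertices score an efficiency
#' of 1.
#'
#' @param n_frontier Number of frontier vertices (at least 2).
#' @param planted_thetas Numeric vector of target scores in `[0, 1)`; may be
#'   empty for a frontier-only panel.
#' @param seed Integer seed.
#' @param max_retries Attempts per planted unit before giving up.
#' @return A list of class `rdm_planted` with elements `panel`, `planted`
#'   (named vector unit id -> intended theta) and `anchors` (data frame of
#'   anchor coordinates).
#' @examples
#' inst <- generate_recovery_instance(4, c(0.3, 0.6), seed = 7)
#' as.data.frame(evaluate_all(inst$panel))
#' @export
generate_recovery_instance <- function(n_frontier, planted_thetas, seed,
                                       max_retries = 100L) {
  stopifnot(n_frontier >= 2)
  if (length(planted_thetas) &&
      (any(planted_thetas < 0) || any(planted_thetas >= 1))) {
    stop("all planted thetas must lie in [0, 1)", call. = FALSE)
  }
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  set.seed(as.integer(seed))
  front <- concave_frontier(n_frontier)
  schema <- rdm_schema(c("x", "y"), c("input", "desirable_output"))
  tab <- front
  planted <- stats::setNames(numeric(0), character(0))
  anchors <- NULL
  for (k in seq_along(planted_thetas)) {
    th <- planted_thetas[k]
    unit <- NULL
    for (try in seq_len(max_retries)) {
      facet <- if (n_frontier == 2) 1L else sample(n_frontier - 1L, 1L)
      alpha <- stats::runif(1, 0.15, 0.85)   # strict facet interior
      p <- c(x = alpha * front$x[facet] + (1 - alpha) * front$x[facet + 1],
             y = alpha * front$y[facet] + (1 - alpha) * front$y[facet + 1])
      cand <- tryCatch(
        plant_inefficient_unit(
          rdm_panel(tab, schema), p, th, id = sprintf("planted_%02d", k)),
        error = function(e) NULL)
      if (!is.null(cand)) {
        unit <- cand
        anchors <- rbind(anchors,
                         data.frame(id = cand$id, x = p[["x"]], y = p[["y"]],
                                    facet = facet, theta = th))
        break
      }
    }
    if (is.null(unit)) {
      stop("could not plant a unit with theta = ", th, " after ",
           max_retries, " attempts", call. = FALSE)
    }
    tab <- rbind(tab, unit)
    planted[unit$id] <- th
  }
  structure(list(panel = rdm_panel(tab, schema), planted = planted,
                 anchors = anchors),
            class = "rdm_planted")
}
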