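#' Variable specifications
#'
#' Builds the per-variable metadata table declaring each variable's role in
#' proxy development and the transform applied before regression.
#'
#' @param name variable names.
#' @param role one of `"output"`, `"candidate"`, `"excluded"` per variable.
#'   Exactly one variable must have role `"output"`.
#' @param transform one of `"log"`, `"identity"`, `"wind_direction"` per
#'   variable. `"wind_direction"` is only valid for angular variables in
#'   degrees `[0, 360)`.
#' @param units free-text units.
#' @return A `data.frame` with class `variable_spec`.
#' @export
variable_spec <- function(name, role, transform = "identity", units = "") {
  role <- match.arg(role, c("output", "candidate", "excluded"),
                    several.ok = TRUE)
  transform <- match.arg(transform, c("log", "identity", "wind_direction"),
                         several.ok = TRUE)
  out <- data.frame(name = as.character(name), role = role,
                    transform = transform, units = units,
                    stringsAsFactors = FALSE)
  if (sum(out$role == "output") != 1L)
    stop("exactly one variable must have role 'output'")
  class(out) <- c("variable_spec", "data.frame")
  out
}

#' @rdname variable_spec
#' @param specs a `variable_spec` table.
#' @export
output_var <- function(specs) specs$name[specs$role == "output"]

#' @rdname variable_spec
#' @export
candidate_vars <- function(specs) specs$name[specs$role == "candidate"]

default_thresholds <- function() {
  list(r_min = 0.1,           # |R| screen for candidate relevance
       vif_max = 5,           # multicollinearity rejection threshold
       alpha = 0.05,          # Lilliefors rejection level
       max_inputs = 3L,       # subset size cap against overfitting
       bootstrap_reps = 5L,   # number of random subsets
       bootstrap_fraction = 0.8,
       min_n = 30L,           # minimum complete rows to fit a model
       min_overlap = 24L,     # minimum pairwise rows for a correlation
       rank_digits = 2L,      # adjR2 rounding granularity for ranking
       season_span_days = 60) # lowess span for the thermal-season curve
}

#' Load a proxy configuration file
#'
#' Parses a YAML configuration declaring the output variable, the candidate
#' predictors, per-variable transforms, screening/rejection thresholds, the
#' public-holiday calendar and the random seed. Absent thresholds default to
#' the standard settings: `r_min = 0.1`, `vif_max = 5`, `alpha = 0.05`,
#' `max_inputs = 3`, `bootstrap_reps = 5`, `bootstrap_fraction = 0.8`,
#' `min_n = 30`, `seed = 0`.
#'
#' @param path YAML file path.
#' @return A list with elements `specs` ([variable_spec]), `thresholds`
#'   (named list), `holidays` (`Date` vector), `seed` (integer) and
#'   `tz_label`.
#' @export
load_config <- function(path) {
  cfg <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop("malformed config '", path, "': ",
                                           conditionMessage(e)))
  if (is.null(cfg$output)) stop("config must name an 'output' variable")
  if (is.null(cfg$candidates)) stop("config must list 'candidates'")
  vars <- c(cfg$output, unlist(cfg$candidates))
  transforms <- vapply(vars, function(v) {
    tr <- cfg$transforms[[v]]
    if (is.null(tr)) "identity" else as.character(tr)
  }, character(1))
  specs <- variable_spec(vars,
                         role = c("output", rep("candidate", length(vars) - 1L)),
                         transform = transforms)
  th <- utils::modifyList(default_thresholds(),
                          cfg$thresholds %||% list())
  th$max_inputs <- as.integer(th$max_inputs)
  if (th$max_inputs < 1L) stop("max_inputs must be >= 1")
  holidays <- if (is.null(cfg$holidays) ||
                  identical(cfg$holidays, "finland_2017_2018")) {
    finnish_holidays()
  } else if (length(cfg$holidays) == 1L && file.exists(cfg$holidays)) {
    read_holiday_file(cfg$holidays)
  } else {
    as.Date(unlist(cfg$holidays))
  }
  list(specs = specs, thresholds = th, holidays = holidays,
       seed = as.integer(cfg$seed %||% 0L),
       season_temp = cfg$season_temp,
       tz_label = cfg$tz_label %||% "UTC+2")
}

read_holiday_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*", "", lines))
  as.Date(lines[nzchar(lines)])
}

#' Finnish public holidays 2017-2018
#'
#' The bundled reference list of Finnish public holidays (including the de
#' facto holidays Midsummer Eve and Christmas Eve) used by
#' [classify_daytype] for the 2017-2018 study calendar.
#'
#' @return A `Date` vector.
#' @export
finnish_holidays <- function() {
  read_holiday_file(system.file("extdata", "finnish_holidays_2017_2018.txt",
                                package = "bcproxy", mustWork = TRUE))
}
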