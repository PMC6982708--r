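#' Fit and quality-control one candidate model
#'
#' The per-model pipeline: complete-case robust fit on the supplied rows,
#' quality control on that full-data fit (VIF of the design, Lilliefors
#' test of the residuals), and — for accepted models — bootstrap-averaged
#' coefficients and evaluation attributes. Models failing any check are
#' returned with `qc$rejected = TRUE` and the reason, never dropped
#' silently.
#'
#' @param data data.frame (transformed scale) holding the inputs and
#'   output.
#' @param inputs character vector of 1-3 input column names.
#' @param output output column name (log scale).
#' @param thresholds threshold list as from [load_config]; see
#'   [default_thresholds][load_config].
#' @param seed seed for the bootstrap subset draws of this model.
#' @return A `candidate_model` object.
#' @export
fit_candidate <- function(data, inputs, output,
                          thresholds = default_thresholds(), seed = 0L) {
  th <- utils::modifyList(default_thresholds(), thresholds)
  model <- structure(list(inputs = inputs, intercept = NA_real_,
                          coefficients = NULL, std_errors = NULL,
                          p_values = NULL, model_p = NA_real_,
                          n_fit = 0L,
                          attributes = list(adjR2 = NA_real_, MAE = NA_real_,
                                            RMSE = NA_real_, MBE = NA_real_),
                          qc = list(vif = NULL, max_vif = NA_real_,
                                    lilliefors_stat = NA_real_,
                                    lilliefors_p = NA_real_,
                                    rejected = TRUE, reason = "")),
                     class = "candidate_model")
  X <- as.matrix(as.data.frame(data)[inputs])
  y <- data[[output]]
  ok <- stats::complete.cases(X) & !is.na(y)
  model$n_fit <- sum(ok)
  if (model$n_fit < th$min_n) {
    model$qc$reason <- "insufficient data"
    return(model)
  }
  full <- tryCatch(fit_robust_ols(X, y, min_n = th$min_n),
                   error = function(e) conditionMessage(e))
  if (is.character(full)) {
    model$qc$reason <- if (grepl("singular", full)) "singular" else full
    return(model)
  }
  v <- vif(X)
  model$qc$vif <- v
  model$qc$max_vif <- max(v)
  lt <- tryCatch(lilliefors(full$residuals,
                            mc_reps = th$lilliefors_mc %||% 0L, seed = seed),
                 error = function(e) NULL)
  if (is.null(lt)) {
    model$qc$reason <- "degenerate residuals"
    return(model)
  }
  model$qc$lilliefors_stat <- lt$statistic
  model$qc$lilliefors_p <- lt$p_value
  if (model$qc$max_vif >= th$vif_max) {
    model$qc$reason <- "multicollinear (VIF)"
    return(model)
  }
  if (lt$p_value < th$alpha) {
    model$qc$reason <- "non-normal residuals"
    return(model)
  }
  boot <- tryCatch(
    bootstrap_fit(X[ok, , drop = FALSE], y[ok], reps = th$bootstrap_reps,
                  fraction = th$bootstrap_fraction, seed = seed,
                  min_n = th$min_n, p_inputs = length(inputs)),
    error = function(e) conditionMessage(e))
  if (is.character(boot)) {
    model$qc$reason <- "insufficient data"
    return(model)
  }
  model$qc$rejected <- FALSE
  model$intercept <- boot$intercept
  model$coefficients <- as.list(boot$coefficients)
  model$std_errors <- as.list(boot$std_errors)
  model$p_values <- as.list(boot$p_values)
  model$model_p <- boot$model_p
  model$attributes <- boot$attributes
  model$full_fit <- list(intercept = full$intercept,
                         coefficients = as.list(full$coefficients),
                         std_errors = as.list(full$std_errors),
                         p_values = as.list(full$p_values),
                         model_p = full$model_p,
                         converged = full$converged,
                         scale = full$scale)
  model$subset_sd <- as.list(apply(
    do.call(rbind, lapply(boot$subsets, function(s) s$fit$coefficients)),
    2, stats::sd))
  model
}

#' Train the input-adaptive proxy
#'
#' Runs the full development chain on a raw table: hourly averaging,
#' per-variable transforms, correlation screening of the candidates
#' against the log output, enumeration of all input subsets up to
#' `max_inputs`, per-class robust fitting with bootstrap averaging,
#' quality control, and ranking — one ranked model set per
#' season-by-daytype class (or a single `"all"` class when no temperature
#' variable is declared for season fitting).
#'
#' @param table raw [timetable] (any spacing up to hourly).
#' @param specs a [variable_spec].
#' @param thresholds threshold list (defaults applied for absent keys).
#' @param holidays public-holiday `Date` vector for daytype
#'   classification.
#' @param temp_var name of the (identity-scale) temperature variable used
#'   to fit thermal seasons; `NULL` disables classification.
#' @param seed master seed for all stochastic steps.
#' @param verbose print per-class progress.
#' @return A `bc_proxy` object: ranked model sets per class plus the
#'   preprocessing artifacts needed to impute (`features`, `boundaries`,
#'   `holidays`, `thresholds`, `specs`, per-class counts).
#' @export
train_proxy <- function(table, specs, thresholds = list(),
                        holidays = finnish_holidays(), temp_var = NULL,
                        seed = 0L, verbose = FALSE) {
  th <- utils::modifyList(default_thresholds(), thresholds)
  hourly <- resample_hourly(table)
  trans <- apply_transforms(hourly, specs)
  out_var <- output_var(specs)
  boundaries <- NULL
  if (!is.null(temp_var)) {
    boundaries <- fit_thermal_seasons(daily_means(hourly, temp_var),
                                      span_days = th$season_span_days)
    classes <- assign_classes(trans, boundaries, holidays)
  } else {
    classes <- rep("all", nrow(trans))
  }
  features <- select_features(trans, out_var,
                              candidates = transformed_candidates(specs),
                              r_min = th$r_min, min_overlap = th$min_overlap)
  subsets <- enumerate_models(features, th$max_inputs)
  ranked <- list()
  counts <- list()
  cls_levels <- sort(unique(classes))
  for (ci in seq_along(cls_levels)) {
    cl <- cls_levels[ci]
    rows <- classes == cl
    dat <- as.data.frame(trans)[rows, c(out_var, features)]
    fitted <- vector("list", length(subsets))
    for (i in seq_along(subsets)) {
      fitted[[i]] <- fit_candidate(dat, subsets[[i]], out_var, th,
                                   seed = seed + 10000L * ci + i)
    }
    reasons <- vapply(fitted, function(m)
      if (isTRUE(m$qc$rejected)) m$qc$reason else "accepted", "")
    counts[[cl]] <- base::table(reasons)
    ranked[[cl]] <- rank_models(fitted, class_label = cl,
                                rank_digits = th$rank_digits)
    if (verbose)
      message(sprintf("[train] class %-16s %d enumerated, %d accepted",
                      cl, length(fitted), length(ranked[[cl]]$models)))
  }
  structure(list(ranked = ranked, features = features,
                 r_values = attr(features, "r_values"),
                 boundaries = boundaries, holidays = as.Date(holidays),
                 thresholds = th, specs = specs, output = out_var,
                 temp_var = temp_var, classes_seen = cls_levels,
                 reject_counts = counts, seed = seed),
            class = "bc_proxy")
}

#' @export
print.bc_proxy <- function(x, ...) {
  cat(sprintf("<bc_proxy> output %s, %d features, %d class(es)\n",
              x$output, length(x$features), length(x$ranked)))
  for (cl in names(x$ranked)) {
    top <- x$ranked[[cl]]$models[[1L]]
    cat(sprintf("  %-18s rank 1: %s (adjR2 %.3f, %d accepted)\n", cl,
                paste(top$inputs, collapse = "+"), top$attributes$adjR2,
                length(x$ranked[[cl]]$models)))
  }
  invisible(x)
}

#' Impute a table with a trained proxy
#'
#' Preprocesses the table the same way as training, assigns classes with
#' the stored season boundaries, and fills the output gaps either
#' adaptively (cascading down the ranking) or traditionally (rank-1
#' only).
#'
#' @param proxy a `bc_proxy` from [train_proxy].
#' @param table raw [timetable].
#' @param mode `"adaptive"` or `"traditional"`.
#' @return As [cascade_impute], plus `coverage` and `classes`.
#' @export
impute_proxy <- function(proxy, table, mode = c("adaptive", "traditional")) {
  mode <- match.arg(mode)
  hourly <- resample_hourly(table)
  trans <- apply_transforms(hourly, proxy$specs)
  classes <- if (is.null(proxy$boundaries)) rep("all", nrow(trans))
             else assign_classes(trans, proxy$boundaries, proxy$holidays)
  missing_cls <- setdiff(unique(classes), names(proxy$ranked))
  if (length(missing_cls))
    stop("class(es) present in data but absent from the trained proxy: ",
         paste(missing_cls, collapse = ", "))
  res <- cascade_impute(trans, proxy$ranked, proxy$output, classes,
                        max_rank = if (mode == "traditional") 1L else Inf)
  res$coverage <- mean(!is.na(res$filled))
  res$classes <- classes
  res
}

#' Tabular model report
#'
#' A per-class table of the top-ranked accepted models with their inputs,
#' bootstrap-averaged coefficients, standard errors, p-values, evaluation
#' attributes and QC values.
#'
#' @param proxy a `bc_proxy`.
#' @param top_k number of models per class (default 10).
#' @return data.frame, one row per (class, model).
#' @export
model_report <- function(proxy, top_k = 10L) {
  rows <- lapply(names(proxy$ranked), function(cl) {
    ms <- utils::head(proxy$ranked[[cl]]$models, top_k)
    do.call(rbind, lapply(ms, function(m) data.frame(
      class = cl, rank = m$rank,
      inputs = paste(m$inputs, collapse = "+"),
      intercept = m$intercept,
      coefficients = paste(sprintf("%s=%.4g", names(m$coefficients),
                                   unlist(m$coefficients)), collapse = ";"),
      std_errors = paste(sprintf("%.3g", unlist(m$std_errors)),
                         collapse = ";"),
      p_values = paste(sprintf("%.3g", unlist(m$p_values)), collapse = ";"),
      model_p = m$model_p,
      adjR2 = m$attributes$adjR2, MAE = m$attributes$MAE,
      RMSE = m$attributes$RMSE, MBE = m$attributes$MBE,
      max_vif = m$qc$max_vif, lilliefors_p = m$qc$lilliefors_p,
      n_fit = m$n_fit, stringsAsFactors = FALSE)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Persist / restore a trained proxy
#'
#' The proxy is serialized as JSON (`models.json`), round-tripping every
#' coefficient at full double precision.
#'
#' @param proxy a `bc_proxy`.
#' @param dir directory to write to (created if needed).
#' @return `proxy_save`: the directory, invisibly. `proxy_load`: the
#'   restored `bc_proxy`.
#' @export
proxy_save <- function(proxy, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  obj <- unclass(proxy)
  obj$ranked <- lapply(obj$ranked, function(rs) {
    rs$models <- lapply(rs$models, unclass)
    unclass(rs)
  })
  obj$specs <- as.list(as.data.frame(obj$specs))
  obj$features <- as.character(obj$features)
  obj$holidays <- as.character(obj$holidays)
  obj$reject_counts <- lapply(obj$reject_counts,
                              function(x) as.list(stats::setNames(as.integer(x), names(x))))
  if (!is.null(obj$boundaries)) {
    b <- obj$boundaries
    obj$boundaries <- list(
      segments = list(start = as.character(b$start),
                      end = as.character(b$end), season = b$season),
      days = as.character(attr(b, "days")),
      season_by_day = attr(b, "season_by_day"),
      span_days = attr(b, "span_days"))
  }
  # I(17) significant digits: doubles survive the text round-trip exactly
  jsonlite::write_json(obj, file.path(dir, "models.json"),
                       auto_unbox = TRUE, digits = I(17), null = "null",
                       na = "null")
  invisible(dir)
}

#' @rdname proxy_save
#' @export
proxy_load <- function(dir) {
  obj <- jsonlite::read_json(file.path(dir, "models.json"),
                             simplifyVector = TRUE, simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  obj$specs <- structure(as.data.frame(obj$specs),
                         class = c("variable_spec", "data.frame"))
  obj$holidays <- as.Date(obj$holidays)
  obj$ranked <- lapply(obj$ranked, function(rs) {
    rs$models <- lapply(rs$models, function(m) {
      m$inputs <- as.character(unlist(m$inputs))
      for (f in c("coefficients", "std_errors", "p_values"))
        m[[f]] <- as.list(unlist(m[[f]]))
      structure(m, class = "candidate_model")
    })
    structure(rs, class = "ranked_model_set")
  })
  if (!is.null(obj$boundaries)) {
    seg <- obj$boundaries$segments
    obj$boundaries <- structure(
      data.frame(start = as.Date(seg$start), end = as.Date(seg$end),
                 season = seg$season, stringsAsFactors = FALSE),
      class = c("season_boundaries", "data.frame"),
      days = as.Date(obj$boundaries$days),
      season_by_day = as.character(unlist(obj$boundaries$season_by_day)),
      span_days = obj$boundaries$span_days)
  }
  structure(obj, class = "bc_proxy")
}
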