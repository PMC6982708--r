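#' Predict the output variable from a candidate model
#'
#' Applies the log-link prediction `exp(b0 + sum(b_i X_i))`: inputs are on
#' their transformed (log) scale, the prediction is a strictly positive
#' concentration on the original scale. Rows where any model input is
#' missing are infeasible and return `NA` rather than raising an error —
#' feasibility is what the cascade tests.
#'
#' @param object a `candidate_model`.
#' @param newdata data.frame (or list) holding the transformed input
#'   columns.
#' @param log_scale if `TRUE`, return the linear predictor without
#'   exponentiation.
#' @param ... unused.
#' @return numeric vector of predictions (`NA` where infeasible).
#' @export
predict.candidate_model <- function(object, newdata, log_scale = FALSE, ...) {
  n <- if (is.data.frame(newdata)) nrow(newdata)
       else if (length(newdata)) NROW(newdata[[1L]]) else 1L
  eta <- rep(object$intercept, n)
  for (nm in object$inputs) {
    v <- newdata[[nm]]
    if (is.null(v)) stop("input '", nm, "' absent from newdata")
    eta <- eta + object$coefficients[[nm]] * v
  }
  if (log_scale) eta else exp(eta)
}

feasible_rows <- function(model, table) {
  ok <- rep(TRUE, nrow(table))
  for (nm in model$inputs) ok <- ok & !is.na(table[[nm]])
  ok
}

#' Cascading (input-adaptive) gap filling
#'
#' Measured output values pass through verbatim. Each missing output slot
#' is filled by the highest-ranked accepted model of its class whose
#' inputs are all present at that timestamp; when the best model's inputs
#' are themselves missing the cascade falls back to the second-best model,
#' and so on down the ranking. Slots no accepted model can serve remain
#' missing and are reported as `unfilled`.
#'
#' @param table transformed [timetable] containing the output column and
#'   all model inputs.
#' @param ranked a `ranked_model_set`, or a named list of them keyed by
#'   class label.
#' @param output name of the (log-scale) output column.
#' @param classes character vector of class labels, one per row; `NULL`
#'   treats all rows as one class (which must then match the single ranked
#'   set supplied).
#' @param max_rank optional cap: only models with rank `<= max_rank` are
#'   used (rank 1 reproduces the traditional proxy).
#' @return list with `filled` (numeric vector on the original scale; `NA`
#'   where unfilled) and `records`, a data.frame with one row per
#'   timestamp: `date`, `value`, `source` (`measured`/`model`/`unfilled`),
#'   `model_rank`, `model_inputs`, `class`.
#' @export
cascade_impute <- function(table, ranked, output, classes = NULL,
                           max_rank = Inf) {
  n <- nrow(table)
  if (is.null(classes)) classes <- rep("all", n)
  stopifnot(length(classes) == n)
  sets <- if (inherits(ranked, "ranked_model_set"))
    stats::setNames(list(ranked), ranked$class_label) else ranked
  miss <- setdiff(unique(classes), names(sets))
  if (length(miss))
    stop("no ranked model set for class(es): ", paste(miss, collapse = ", "))
  y_log <- table[[output]]
  value <- ifelse(is.na(y_log), NA_real_, exp(y_log))
  source <- ifelse(is.na(y_log), "unfilled", "measured")
  rank_used <- rep(NA_integer_, n)
  inputs_used <- rep(NA_character_, n)
  for (cl in unique(classes)) {
    rows_cl <- which(classes == cl & is.na(y_log))
    if (!length(rows_cl)) next
    open <- rows_cl
    for (m in sets[[cl]]$models) {
      if (m$rank > max_rank) break
      if (!length(open)) break
      feas <- open[feasible_rows(m, table[open, , drop = FALSE])]
      if (!length(feas)) next
      value[feas] <- predict(m, table[feas, , drop = FALSE])
      source[feas] <- "model"
      rank_used[feas] <- m$rank
      inputs_used[feas] <- paste(m$inputs, collapse = "+")
      open <- setdiff(open, feas)
    }
  }
  records <- data.frame(date = table$date, value = value, source = source,
                        model_rank = rank_used, model_inputs = inputs_used,
                        class = classes, stringsAsFactors = FALSE)
  list(filled = value, records = records)
}

#' Traditional (single best model) gap filling
#'
#' The cascade restricted to the rank-1 model of each class: gaps whose
#' best-model inputs are missing stay unfilled, which is exactly the
#' coverage limitation the adaptive cascade removes.
#'
#' @inheritParams cascade_impute
#' @return As [cascade_impute], plus `coverage`: the fraction of
#'   timestamps with a value (measured or filled).
#' @export
traditional_impute <- function(table, ranked, output, classes = NULL) {
  out <- cascade_impute(table, ranked, output, classes, max_rank = 1L)
  out$coverage <- mean(!is.na(out$filled))
  out
}

#' Rank-usage summary of a cascade run
#'
#' For each class, the fraction of gap timestamps filled by the rank-1
#' model, the rank-2 model, ranks 3-10, ranks beyond 10, or left unfilled.
#' Fractions sum to 1 per class over the gap slots.
#'
#' @param records the `records` data.frame from [cascade_impute].
#' @return data.frame with columns `class`, `bucket`, `fraction`, `n`.
#' @export
rank_usage <- function(records) {
  gaps <- records[records$source != "measured", , drop = FALSE]
  buckets <- c("1", "2", "3-10", ">10", "unfilled")
  res <- lapply(split(gaps, gaps$class), function(g) {
    b <- ifelse(g$source == "unfilled", "unfilled",
         ifelse(g$model_rank == 1L, "1",
         ifelse(g$model_rank == 2L, "2",
         ifelse(g$model_rank <= 10L, "3-10", ">10"))))
    cnt <- base::table(factor(b, levels = buckets))
    data.frame(class = g$class[1L], bucket = buckets,
               fraction = as.numeric(cnt) / nrow(g),
               n = as.integer(cnt), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Diurnal profile of an hourly series
#'
#' Per-hour-of-day arithmetic mean and standard deviation over the
#' timestamps of one class (or all timestamps), skipping missing values.
#'
#' @param dates POSIXct timestamps (hourly).
#' @param values numeric series aligned with `dates`.
#' @param classes optional class labels per timestamp.
#' @param class_label class to profile; `NULL` profiles everything.
#' @return data.frame with `hour` (0-23), `mean`, `sd`, `n`; `mean` is
#'   `NA` for hours with no data.
#' @export
diurnal_profile <- function(dates, values, classes = NULL,
                            class_label = NULL) {
  keep <- if (is.null(class_label)) rep(TRUE, length(dates))
          else classes == class_label
  hr <- as.POSIXlt(dates[keep], tz = "UTC")$hour
  v <- values[keep]
  f <- factor(hr, levels = 0:23)
  n <- tapply(!is.na(v), f, sum)
  n[is.na(n)] <- 0
  data.frame(
    hour = 0:23,
    mean = as.numeric(tapply(v, f, function(x)
      if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE))),
    sd = as.numeric(tapply(v, f, function(x)
      if (sum(!is.na(x)) < 2L) NA_real_ else stats::sd(x, na.rm = TRUE))),
    n = as.integer(n)
  )
}
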