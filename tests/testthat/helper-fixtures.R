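# Shared fixtures: everything is built in code at test time.

# A small hourly timetable with the given columns.
make_tt <- function(n = 48L, ..., start = "2017-01-01 00:00:00") {
  timetable(as.POSIXct(start, tz = "UTC") + 3600 * (seq_len(n) - 1L), ...)
}

# A hand-built accepted candidate model with chosen attributes.
make_model <- function(inputs, intercept = 0, coefficients = NULL,
                       adjR2 = 0.9, MAE = 0.01, RMSE = 0.2, n_fit = 500L) {
  if (is.null(coefficients))
    coefficients <- stats::setNames(as.list(rep(1, length(inputs))), inputs)
  structure(list(inputs = inputs, intercept = intercept,
                 coefficients = as.list(coefficients),
                 std_errors = as.list(rep(0.1, length(inputs))),
                 p_values = as.list(rep(0.001, length(inputs))),
                 model_p = 0.001, n_fit = n_fit,
                 attributes = list(adjR2 = adjR2, MAE = MAE, RMSE = RMSE,
                                   MBE = 0),
                 qc = list(max_vif = 1, lilliefors_p = 0.5,
                           rejected = FALSE, reason = "")),
            class = "candidate_model")
}

# Quick small synthetic study (4 months, 5 predictors, 2 true inputs).
small_synth <- function(seed = 1L, ...) {
  cfg <- synth_config(start = "2017-01-01", end = "2017-04-30",
                      n_predictors = 5L, true_inputs = c("X1", "X2"),
                      beta = c(X1 = 0.6, X2 = 0.3), seed = seed, ...)
  generate_synthetic(cfg)
}
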