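#' Variance inflation factors
#'
#' For each design column, regress it (unweighted least squares, with
#' intercept) on the remaining columns; the VIF is `1 / (1 - R_p^2)` where
#' `R_p^2` is the auxiliary coefficient of determination. A single-input
#' model has VIF 1 by definition; exactly collinear columns yield `Inf`.
#'
#' @param X numeric matrix of input columns (complete rows are used).
#' @return named numeric vector of VIFs, one per column, each `>= 1`.
#' @export
vif <- function(X) {
  X <- as.matrix(X)
  X <- X[stats::complete.cases(X), , drop = FALSE]
  p <- ncol(X)
  nms <- colnames(X) %||% paste0("X", seq_len(p))
  if (p == 1L) return(stats::setNames(1, nms))
  out <- numeric(p)
  for (j in seq_len(p)) {
    xj <- X[, j]
    others <- cbind(1, X[, -j, drop = FALSE])
    fit <- stats::lm.fit(others, xj)
    tss <- sum((xj - mean(xj))^2)
    rss <- sum(fit$residuals^2)
    r2 <- if (tss == 0) 1 else 1 - rss / tss
    out[j] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  stats::setNames(pmax(out, 1), nms)
}

#' Lilliefors test for residual normality
#'
#' Kolmogorov-Smirnov-type test with mean and standard deviation estimated
#' from the sample: residuals are z-scored and the statistic is the
#' sup-distance between the empirical distribution of the z-scores and the
#' standard normal. Because the parameters are estimated, the plain K-S
#' null distribution does not apply; the p-value comes either from a
#' seeded Monte Carlo null table (`mc_reps > 0`) or from the
#' Dallal-Wilkinson analytic approximation (`mc_reps = 0`, the fast
#' default, via \pkg{nortest}).
#'
#' @param x numeric vector (n >= 8 recommended); NAs dropped.
#' @param mc_reps Monte Carlo replicates for the null table; 0 uses the
#'   analytic approximation.
#' @param seed seed for the Monte Carlo draws.
#' @return list with `statistic` and `p_value`.
#' @export
lilliefors <- function(x, mc_reps = 0L, seed = 0L) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 5L) stop("lilliefors test needs at least 5 observations")
  if (stats::sd(x) == 0) stop("zero-variance sample: normality test degenerate")
  D <- lillie_stat(x)
  p <- if (mc_reps > 0L) {
    rng <- local_rng(seed)
    exceed <- 0L
    for (b in seq_len(mc_reps)) {
      z <- rng$rnorm(n)
      if (lillie_stat(z) >= D) exceed <- exceed + 1L
    }
    (exceed + 1) / (mc_reps + 1)
  } else {
    nortest::lillie.test(x)$p.value
  }
  list(statistic = D, p_value = min(max(p, 0), 1))
}

lillie_stat <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / stats::sd(x))
  Phi <- stats::pnorm(z)
  max(seq_len(n) / n - Phi, Phi - (seq_len(n) - 1) / n)
}

#' Evaluation attributes of a fitted model
#'
#' Computed on the scale the model was fitted on (the log scale for
#' log-transformed outputs): adjusted R-squared from the squared
#' correlation of measured and estimated series, penalized by the degrees
#' of freedom, `adjR2 = 1 - (1 - r^2) (N - 1)/(N - p - 1)`; mean absolute
#' error; root mean square error; and the signed mean error (MBE,
#' estimated minus measured) as a bias diagnostic.
#'
#' @param y measured series.
#' @param yhat estimated series (aligned; incomplete pairs dropped).
#' @param p number of model inputs.
#' @return list with `adjR2`, `MAE`, `RMSE`, `MBE`. `adjR2` is `NA` when
#'   either series is constant (undefined correlation).
#' @export
evaluate_fit <- function(y, yhat, p) {
  ok <- !is.na(y) & !is.na(yhat)
  y <- y[ok]; yhat <- yhat[ok]
  n <- length(y)
  if (n < p + 2L) stop("need at least p + 2 complete pairs")
  d <- yhat - y
  adjR2 <- if (stats::sd(y) == 0 || stats::sd(yhat) == 0) NA_real_ else
    1 - (1 - stats::cor(y, yhat)^2) * (n - 1) / (n - p - 1)
  list(adjR2 = adjR2,
       MAE = mean(abs(d)),
       RMSE = sqrt(mean(d^2)),
       MBE = mean(d))
}

#' Rank accepted models
#'
#' Rejected models are dropped; the rest are ordered by adjusted R-squared
#' (rounded to `rank_digits` decimals, so near-ties are genuine ties)
#' descending, then MAE ascending, then RMSE ascending, then number of
#' fitted rows descending (more data lowers uncertainty), then input names
#' lexicographically for full determinism. Ranks 1..K are assigned.
#'
#' @param models list of `candidate_model` objects.
#' @param class_label label of the class the models belong to.
#' @param rank_digits rounding granularity for the adjusted R-squared
#'   comparison (default 2).
#' @return A `ranked_model_set`: list with `class_label`, `models` (rank 1
#'   first, each carrying its `rank`), and `ranking_criteria`.
#' @export
rank_models <- function(models, class_label = "all", rank_digits = 2L) {
  keep <- Filter(function(m) !isTRUE(m$qc$rejected) &&
                   !is.na(m$attributes$adjR2), models)
  if (length(keep) == 0L)
    stop("no accepted model for class '", class_label, "'")
  key <- data.frame(
    adj = -round(vapply(keep, function(m) m$attributes$adjR2, 0), rank_digits),
    mae = vapply(keep, function(m) m$attributes$MAE, 0),
    rmse = vapply(keep, function(m) m$attributes$RMSE, 0),
    n = -vapply(keep, function(m) m$n_fit, 0),
    nm = vapply(keep, function(m) paste(sort(m$inputs), collapse = "+"), "")
  )
  ord <- do.call(order, key)
  ranked <- keep[ord]
  for (i in seq_along(ranked)) ranked[[i]]$rank <- i
  structure(list(class_label = class_label, models = ranked,
                 ranking_criteria = list(adjR2_digits = rank_digits,
                                         order = c("adjR2 desc", "MAE asc",
                                                   "RMSE asc", "n_fit desc",
                                                   "inputs lex"))),
            class = "ranked_model_set")
}

#' @export
print.ranked_model_set <- function(x, ...) {
  cat(sprintf("<ranked_model_set> class %s: %d accepted models\n",
              x$class_label, length(x$models)))
  top <- utils::head(x$models, 5L)
  for (m in top)
    cat(sprintf("  #%d %s  adjR2=%.3f MAE=%.4f RMSE=%.4f n=%d\n",
                m$rank, paste(m$inputs, collapse = "+"),
                m$attributes$adjR2, m$attributes$MAE, m$attributes$RMSE,
                m$n_fit))
  invisible(x)
}
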