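#' Pairwise-complete Pearson correlation
#'
#' Product-moment correlation over the rows where both series are present.
#' Returns `NA` (undefined) when fewer than `min_overlap` complete pairs
#' exist or either series is constant over the overlap.
#'
#' @param x,y numeric vectors of equal length.
#' @param min_overlap minimum number of complete pairs.
#' @return correlation in `[-1, 1]`, or `NA` if undefined.
#' @export
pearson_r <- function(x, y, min_overlap = 24L) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < max(2L, min_overlap)) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Screen candidate predictors by correlation with the output
#'
#' Computes the pairwise-complete Pearson correlation of each candidate
#' column against the (transformed) output column and keeps those with
#' `|R| >= r_min`, ordered by `|R|` descending with alphabetical
#' tie-breaking. Weakly correlated variables are discarded up front to
#' bound the number of candidate models.
#'
#' @param table transformed [timetable] (or data.frame of aligned columns).
#' @param output name of the output column.
#' @param candidates names of candidate columns (default: all others).
#' @param r_min absolute-correlation threshold.
#' @param min_overlap passed to [pearson_r].
#' @return character vector of surviving candidate names, with the full
#'   correlation table in the `r_values` attribute.
#' @export
select_features <- function(table, output, candidates = NULL,
                            r_min = 0.1, min_overlap = 24L) {
  if (is.null(candidates))
    candidates <- setdiff(names(table), c("date", output))
  r <- vapply(candidates, function(nm)
    pearson_r(table[[nm]], table[[output]], min_overlap), numeric(1))
  keep <- !is.na(r) & abs(r) >= r_min
  if (!any(keep)) {
    msg <- paste(sprintf("%s: R = %.3f", candidates, r), collapse = "\n  ")
    stop("no candidate passes the |R| >= ", r_min, " screen:\n  ", msg)
  }
  ord <- order(-abs(r[keep]), candidates[keep])
  structure(candidates[keep][ord], r_values = r)
}

#' Enumerate candidate input subsets
#'
#' All subsets of 1 to `max_inputs` features, in deterministic order:
#' increasing subset size, then lexicographic within a size.
#'
#' @param features character vector of feature names.
#' @param max_inputs maximum subset size (default 3).
#' @return list of character vectors, one per candidate model.
#' @export
enumerate_models <- function(features, max_inputs = 3L) {
  stopifnot(length(features) > 0L, max_inputs >= 1L)
  features <- sort(features)
  out <- list()
  for (k in seq_len(min(max_inputs, length(features))))
    out <- c(out, utils::combn(features, k, simplify = FALSE))
  out
}

#' Tukey bisquare weight
#'
#' `w(r) = (1 - (r/c)^2)^2` for `|r| <= c`, zero beyond: residuals past the
#' tuning constant lose all influence on the fit.
#'
#' @param r standardized adjusted residuals.
#' @param c_tuning tuning constant (default 4.685, the conventional value
#'   giving 95% efficiency under Gaussian errors).
#' @return weights in `[0, 1]`.
#' @export
bisquare_weight <- function(r, c_tuning = 4.685) {
  w <- (1 - (r / c_tuning)^2)^2
  w[abs(r) > c_tuning] <- 0
  w
}

#' Robust linear regression by iteratively reweighted least squares
#'
#' Fits `y = b0 + X b + e` starting from the unweighted least-squares
#' solution. Each iteration computes residuals, the robust scale
#' `s = MAD / 0.6745`, standardized adjusted residuals
#' `r_i = e_i / (s * sqrt(1 - h_i))` (with `h_i` the leverages of the
#' design), Tukey bisquare weights with tuning constant `c`, and refits by
#' weighted least squares, until the coefficients move by less than `tol`
#' (relative) or `max_iter` is reached. Standard errors come from the
#' weighted normal equations with the robust scale as residual standard
#' deviation, and p-values from a t reference with `n - p - 1` degrees of
#' freedom.
#'
#' @param X numeric matrix of input columns (no intercept column).
#' @param y numeric response vector.
#' @param c_tuning bisquare tuning constant.
#' @param max_iter,tol convergence controls.
#' @param min_n minimum complete rows required.
#' @return A `robust_fit` list: `intercept`, `coefficients`, `std_errors`,
#'   `p_values`, `model_p`, `residuals`, `final_weights`, `scale`,
#'   `leverages`, `n_fit`, `iterations`, `converged`, `fitted`.
#' @export
fit_robust_ols <- function(X, y, c_tuning = 4.685, max_iter = 50L,
                           tol = 1e-6, min_n = 30L) {
  X <- as.matrix(X)
  ok <- stats::complete.cases(X) & !is.na(y)
  X <- X[ok, , drop = FALSE]; y <- y[ok]
  n <- length(y); p <- ncol(X)
  if (n < max(min_n, p + 2L))
    stop("insufficient complete rows (", n, ") to fit a ", p, "-input model")
  Xd <- cbind(`(Intercept)` = 1, X)
  qrX <- qr(Xd)
  if (qrX$rank < ncol(Xd)) stop("singular design")
  h <- pmin(rowSums(qr.Q(qrX)[, seq_len(qrX$rank), drop = FALSE]^2),
            1 - 1e-8)
  beta <- qr.coef(qrX, y)
  w <- rep(1, n)
  converged <- FALSE
  iter <- 0L
  s <- 1
  repeat {
    e <- y - drop(Xd %*% beta)
    s <- stats::median(abs(e - stats::median(e))) / 0.6745
    if (s <= 1e-8 * max(1, stats::median(abs(y)))) {
      # (near-)exact fit: nothing to downweight
      w <- rep(1, n); converged <- TRUE; break
    }
    r <- e / (s * sqrt(1 - h))
    w <- bisquare_weight(r, c_tuning)
    if (all(w == 0)) stop("degenerate robust fit: all weights zero")
    fit <- stats::lm.wfit(Xd, y, w)
    beta_new <- fit$coefficients
    if (max(abs(beta_new - beta) / pmax(1, abs(beta))) < tol) {
      beta <- beta_new; converged <- TRUE
      e <- y - drop(Xd %*% beta)
      r <- e / (s * sqrt(1 - h))
      w <- bisquare_weight(r, c_tuning)
      break
    }
    beta <- beta_new
    iter <- iter + 1L
    if (iter >= max_iter) break
  }
  e <- y - drop(Xd %*% beta)
  df <- n - p - 1L
  # residual variance from the robust (MAD-based) scale: the weighted RSS
  # underestimates sigma once the bisquare has downweighted the tails
  sigma2 <- max(s, 1e-300)^2
  XtWX <- crossprod(Xd, Xd * w)
  covb <- sigma2 * chol2inv(chol(XtWX))
  se <- sqrt(diag(covb))
  tval <- beta / se
  pvals <- 2 * stats::pt(-abs(tval), df)
  # overall weighted F test against the intercept-only model
  ybar_w <- sum(w * y) / sum(w)
  tss <- sum(w * (y - ybar_w)^2)
  rss <- sum(w * e^2)
  fstat <- ((tss - rss) / p) / (rss / df)
  model_p <- stats::pf(fstat, p, df, lower.tail = FALSE)
  structure(list(
    intercept = unname(beta[1L]),
    coefficients = beta[-1L],
    std_errors = se[-1L],
    intercept_se = unname(se[1L]),
    p_values = pvals[-1L],
    intercept_p = unname(pvals[1L]),
    model_p = model_p,
    residuals = e,
    final_weights = w,
    scale = s,
    leverages = h,
    fitted = drop(Xd %*% beta),
    n_fit = n,
    iterations = iter,
    converged = converged
  ), class = "robust_fit")
}

#' Bootstrap-averaged robust fit
#'
#' Draws `reps` independent random subsets, each a fraction `fraction` of
#' the complete rows (without replacement within a subset), robust-fits
#' each, and averages coefficients, standard errors and evaluation
#' attributes arithmetically across subsets. Averaging over subsets damps
#' the sensitivity of any single fit to the particular rows available.
#'
#' @param X,y as in [fit_robust_ols] (complete rows are selected
#'   internally).
#' @param reps number of subsets (default 5).
#' @param fraction subset fraction of the data (default 0.8);
#'   `fraction = 1` reduces to a single full-data fit per subset.
#' @param seed integer seed governing the subset draws.
#' @param min_n subsets with fewer complete rows are skipped with a
#'   warning.
#' @param p_inputs number of inputs, used by the adjusted R-squared.
#' @param ... passed to [fit_robust_ols].
#' @return list with averaged `intercept`, `coefficients`, `std_errors`,
#'   `p_values`, `model_p`, `attributes` (adjR2/MAE/RMSE/MBE averaged on
#'   the fitting scale), `n_fit` (complete rows), `subsets` (per-subset
#'   results for dispersion reporting).
#' @export
bootstrap_fit <- function(X, y, reps = 5L, fraction = 0.8, seed = 0L,
                          min_n = 30L, p_inputs = NULL, ...) {
  stopifnot(reps >= 1L, fraction > 0, fraction <= 1)
  X <- as.matrix(X)
  ok <- stats::complete.cases(X) & !is.na(y)
  X <- X[ok, , drop = FALSE]; y <- y[ok]
  n <- nrow(X)
  if (is.null(p_inputs)) p_inputs <- ncol(X)
  m <- ceiling(fraction * n)
  rng <- local_rng(seed)
  subsets <- vector("list", reps)
  for (b in seq_len(reps)) {
    rows <- if (m >= n) seq_len(n) else rng$sample(n, m)
    if (length(rows) < max(min_n, ncol(X) + 2L)) {
      warning("bootstrap subset ", b, " below min_n; skipped")
      next
    }
    fit <- tryCatch(
      fit_robust_ols(X[rows, , drop = FALSE], y[rows], min_n = min_n, ...),
      error = function(e) NULL)
    if (is.null(fit)) { warning("bootstrap subset ", b, " failed; skipped"); next }
    att <- evaluate_fit(y[rows], fit$fitted, p_inputs)
    subsets[[b]] <- list(fit = fit, attributes = att)
  }
  subsets <- Filter(Negate(is.null), subsets)
  if (length(subsets) == 0L)
    stop("insufficient data: every bootstrap subset failed")
  avg <- function(f) {
    vals <- do.call(rbind, lapply(subsets, f))
    colMeans(vals)
  }
  co <- avg(function(s) s$fit$coefficients)
  list(
    intercept = mean(vapply(subsets, function(s) s$fit$intercept, 0)),
    coefficients = co,
    std_errors = avg(function(s) s$fit$std_errors),
    p_values = avg(function(s) s$fit$p_values),
    model_p = mean(vapply(subsets, function(s) s$fit$model_p, 0)),
    attributes = as.list(avg(function(s) unlist(s$attributes))),
    n_fit = n,
    n_subsets = length(subsets),
    subsets = subsets
  )
}

# Seed-scoped RNG helper: draws do not disturb the global RNG stream.
local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, envir = globalenv())
  with_state <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    expr
  }
  list(
    sample = function(n, size) with_state(sample.int(n, size)),
    runif = function(n) with_state(stats::runif(n)),
    rnorm = function(n) with_state(stats::rnorm(n))
  )
}
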