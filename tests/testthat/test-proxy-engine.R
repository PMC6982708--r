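test_that("pearson_r matches the product-moment definition", {
  x <- c(1, 2, 3, 4); y <- c(1, 2, 2, 4)
  # direct evaluation of the covariance / sd ratio
  num <- sum((x - mean(x)) * (y - mean(y)))
  den <- sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_r(x, y, min_overlap = 2), num / den)
  expect_equal(pearson_r(x, x, min_overlap = 2), 1)
  expect_equal(pearson_r(x, -2 * x + 3, min_overlap = 2), -1)
})

test_that("pearson_r is undefined below min_overlap or for constant series", {
  x <- c(1, 2, 3, NA, NA); y <- c(2, 4, NA, 1, 1)
  expect_true(is.na(pearson_r(x, y, min_overlap = 3)))   # only 2 overlap
  expect_true(is.na(pearson_r(rep(1, 30), rnorm(30))))
})

test_that("pearson_r is symmetric and affine-invariant", {
  set.seed(7)
  for (i in 1:20) {
    x <- rnorm(40); y <- rnorm(40)
    a <- runif(1, 0.1, 5); b <- rnorm(1)
    expect_equal(pearson_r(x, y, 2), pearson_r(y, x, 2))
    expect_equal(pearson_r(a * x + b, y, 2), pearson_r(x, y, 2))
  }
})

test_that("feature screening keeps |R| >= r_min ordered by |R| then name", {
  set.seed(11)
  n <- 2000
  strong <- rnorm(n)
  y <- strong + 0.5 * rnorm(n)
  mid <- y + 2.2 * rnorm(n)
  weak <- rnorm(n)                      # ~0 correlation
  tab <- data.frame(y = y, a_strong = strong, b_mid = mid, c_weak = weak)
  sel <- select_features(tab, "y", r_min = 0.1, min_overlap = 24)
  expect_equal(as.character(sel), c("a_strong", "b_mid"))
  r <- attr(sel, "r_values")
  expect_lt(abs(r["c_weak"]), 0.1)
  # a candidate equal to the output comes first with |R| = 1
  tab$zz_copy <- y
  sel2 <- select_features(tab, "y")
  expect_equal(as.character(sel2)[1], "zz_copy")
  expect_equal(unname(attr(sel2, "r_values")["zz_copy"]), 1)
  # no survivor is fatal, with the R table in the message
  expect_error(select_features(data.frame(y = y, c_weak = weak), "y"),
               "c_weak")
})

test_that("model enumeration covers all subsets of size 1..max in fixed order", {
  expect_length(enumerate_models(letters[1:3], 3), 7L)
  expect_length(enumerate_models("solo", 3), 1L)
  expect_length(enumerate_models(paste0("f", 1:19), 3),
                choose(19, 1) + choose(19, 2) + choose(19, 3))
  m <- enumerate_models(c("b", "a", "c"), 2)
  expect_equal(m, list("a", "b", "c", c("a", "b"), c("a", "c"), c("b", "c")))
  for (k in 1:4) {
    feats <- paste0("v", 1:6)
    expect_length(enumerate_models(feats, k),
                  sum(choose(6, seq_len(k))))
  }
})

test_that("bisquare weight has the closed form with c = 4.685", {
  expect_equal(bisquare_weight(0), 1)
  expect_equal(bisquare_weight(4.685), 0)
  expect_equal(bisquare_weight(4.685 / 2), 0.5625)
  expect_equal(bisquare_weight(10), 0)
  r <- seq(-6, 6, by = 0.1)
  w <- bisquare_weight(r)
  expect_true(all(w >= 0 & w <= 1))
  expect_true(all((w == 0) == (abs(r) > 4.685)))
})

test_that("robust fit reproduces exact linear data and matches OLS when clean", {
  set.seed(3)
  n <- 200
  X <- cbind(a = rnorm(n), b = runif(n))
  y_exact <- 1.5 - 2 * X[, "a"] + 0.5 * X[, "b"]
  fit <- fit_robust_ols(X, y_exact)
  expect_equal(fit$intercept, 1.5, tolerance = 1e-8)
  expect_equal(unname(fit$coefficients), c(-2, 0.5), tolerance = 1e-8)
  expect_true(all(fit$final_weights == 1))
  # noise-free data: robust and unweighted OLS coincide exactly
  ols0 <- stats::lm.fit(cbind(1, X), y_exact)$coefficients
  expect_lt(max(abs(c(fit$intercept, fit$coefficients) - ols0)), 1e-6)
  # moderate Gaussian noise, no gross outliers: the bisquare reweighting
  # is mild, so the robust fit stays close to plain OLS
  y <- y_exact + 0.1 * rnorm(n)
  ols <- stats::lm.fit(cbind(1, X), y)$coefficients
  fit2 <- fit_robust_ols(X, y)
  expect_equal(unname(c(fit2$intercept, fit2$coefficients)),
               unname(ols), tolerance = 0.02)
})

test_that("robust fit resists gross outliers where plain OLS does not", {
  set.seed(5)
  n <- 500
  x <- rnorm(n)
  y <- 1 + 2 * x + 0.1 * rnorm(n)
  out_idx <- sample(n, 50)             # 10% gross outliers, offset +10
  y[out_idx] <- y[out_idx] + 10
  fit <- fit_robust_ols(cbind(x = x), y)
  ols_slope <- stats::coef(stats::lm(y ~ x))[["x"]]
  expect_lt(abs(fit$coefficients[["x"]] - 2), 0.05)
  expect_gt(abs(ols_slope - 2), abs(fit$coefficients[["x"]] - 2))
  expect_true(all(fit$final_weights[out_idx] < 0.5))
})

test_that("robust fit agrees with an independent bisquare implementation", {
  skip_if_not_installed("MASS")
  set.seed(9)
  n <- 400
  X <- cbind(a = rnorm(n), b = rnorm(n))
  y <- 0.5 + X[, "a"] - 0.7 * X[, "b"] + 0.2 * rnorm(n)
  y[1:20] <- y[1:20] + 5
  fit <- fit_robust_ols(X, y)
  rlm <- MASS::rlm(y ~ X, psi = MASS::psi.bisquare, maxit = 100)
  expect_equal(unname(c(fit$intercept, fit$coefficients)),
               unname(stats::coef(rlm)), tolerance = 0.02)
})

test_that("robust fit rejects unusable designs", {
  x <- rnorm(100)
  expect_error(fit_robust_ols(cbind(a = x, b = 2 * x), x + rnorm(100)),
               "singular")
  expect_error(fit_robust_ols(cbind(a = rnorm(10)), rnorm(10), min_n = 30),
               "insufficient")
})

test_that("bootstrap averaging: fraction 1 collapses to the single fit", {
  set.seed(13)
  n <- 150
  X <- cbind(a = rnorm(n))
  y <- 2 + 3 * X[, "a"] + 0.3 * rnorm(n)
  single <- fit_robust_ols(X, y)
  boot <- bootstrap_fit(X, y, reps = 3, fraction = 1, seed = 4)
  expect_equal(boot$intercept, single$intercept)
  expect_equal(boot$coefficients, single$coefficients)
})

test_that("bootstrap averaging is seed-deterministic and near the full fit", {
  set.seed(17)
  n <- 400
  X <- cbind(a = rnorm(n), b = rnorm(n))
  y <- 1 + 0.8 * X[, "a"] - 0.4 * X[, "b"] + 0.2 * rnorm(n)
  b1 <- bootstrap_fit(X, y, seed = 42)
  b2 <- bootstrap_fit(X, y, seed = 42)
  expect_identical(b1$coefficients, b2$coefficients)
  expect_identical(b1$attributes, b2$attributes)
  b3 <- bootstrap_fit(X, y, seed = 43)
  expect_false(identical(b1$coefficients, b3$coefficients))
  full <- fit_robust_ols(X, y)
  subset_sd <- apply(do.call(rbind, lapply(b1$subsets,
                                           function(s) s$fit$coefficients)),
                     2, sd)
  expect_true(all(abs(b1$coefficients - full$coefficients) <= 3 * subset_sd))
})

test_that("robust coefficient recovery stays inside reported 95% intervals", {
  # 100 seeded replicates of a known 3-input Gaussian model; per-coefficient
  # coverage of the t-based intervals should be near nominal
  covered <- 0L; total <- 0L
  beta <- c(0.6, 0.3, 0.2)
  for (rep in 1:100) {
    set.seed(1000 + rep)
    n <- 300
    X <- matrix(rnorm(n * 3), n, 3) %*% chol(0.4 + diag(0.6, 3))
    colnames(X) <- c("a", "b", "c")
    y <- 0.2 + drop(X %*% beta) + 0.2 * rnorm(n)
    fit <- fit_robust_ols(X, y)
    half <- qt(0.975, fit$n_fit - 4) * fit$std_errors
    covered <- covered + sum(abs(fit$coefficients - beta) <= half)
    total <- total + 3L
  }
  expect_gte(covered / total, 0.9)
})
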