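test_that("log-link prediction exponentiates the linear predictor", {
  m0 <- make_model(character(0), intercept = 0, coefficients = list())
  expect_equal(predict(m0, data.frame(x = 1:3)), rep(1, 3))
  m1 <- make_model("x", intercept = log(2), coefficients = list(x = 1))
  expect_equal(predict(m1, data.frame(x = 0)), 2)
  expect_equal(predict(m1, data.frame(x = c(1, NA))), c(2 * exp(1), NA))
  expect_equal(predict(m1, data.frame(x = 1), log_scale = TRUE), log(2) + 1)
})

test_that("prediction reproduces the generator's noiseless values", {
  cfg <- synth_config(start = "2017-01-01", end = "2017-01-15",
                      n_predictors = 3, true_inputs = c("X1", "X2"),
                      beta = c(X1 = 0.6, X2 = 0.3), noise_sd = 0,
                      gap_spec = list(), seed = 2)
  g <- generate_synthetic(cfg)
  trans <- apply_transforms(g$truth, synth_specs(cfg))
  truth_model <- make_model(c("X1", "X2"), intercept = cfg$beta0,
                            coefficients = as.list(cfg$beta))
  expect_equal(predict(truth_model, as.data.frame(trans)),
               as.data.frame(g$truth)$BC, tolerance = 1e-10)
})

# A hand-built two-model cascade fixture: y missing on chosen rows, with
# rank-1 inputs masked on some of them so the fallback is forced.
cascade_fixture <- function() {
  n <- 60L
  tt <- make_tt(n,
                y = log(seq(1, 2, length.out = n)),
                a = rnorm(n), b = rnorm(n), c = rnorm(n))
  tt$y[11:30] <- NA                      # 20 gap slots
  tt$a[11:20] <- NA                      # rank-1 infeasible on 10 of them
  tt$c[15] <- NA                         # rank-2 also infeasible at slot 15
  rank1 <- make_model("a", intercept = 0.1, coefficients = list(a = 0.5),
                      adjR2 = 0.95)
  rank2 <- make_model("c", intercept = 0.2, coefficients = list(c = 0.3),
                      adjR2 = 0.80)
  rs <- rank_models(list(rank2, rank1), "all")
  list(tt = tt, rs = rs)
}

test_that("cascade fills with the best feasible model and reports the rest", {
  f <- cascade_fixture()
  res <- cascade_impute(f$tt, f$rs, "y")
  rec <- res$records
  expect_equal(sum(rec$source == "measured"), 40L)
  # measured slots pass through verbatim (exp of the log column)
  expect_equal(res$filled[rec$source == "measured"],
               exp(f$tt$y[!is.na(f$tt$y)]))
  expect_equal(rec$model_rank[11:14], rep(2L, 4))   # a missing, c present
  expect_true(is.na(res$filled[15]))                # nothing feasible
  expect_equal(rec$source[15], "unfilled")
  expect_equal(rec$model_rank[16:20], rep(2L, 5))
  expect_equal(rec$model_rank[21:30], rep(1L, 10))  # rank 1 feasible again
  # filled values equal the models' own predictions
  expect_equal(res$filled[21:30], exp(0.1 + 0.5 * f$tt$a[21:30]))
  expect_equal(res$filled[11:14], exp(0.2 + 0.3 * f$tt$c[11:14]))
})

test_that("cascade feasibility is optimal against a brute-force scan", {
  g <- small_synth(seed = 3)
  trans <- apply_transforms(g$table, synth_specs(g$config))
  models <- list(
    make_model(c("X1", "X2"), adjR2 = 0.95,
               coefficients = list(X1 = 0.6, X2 = 0.3)),
    make_model("X1", adjR2 = 0.90, coefficients = list(X1 = 0.7)),
    make_model("X4", adjR2 = 0.60, coefficients = list(X4 = 0.5)))
  rs <- rank_models(models, "all")
  res <- cascade_impute(trans, rs, "BC")
  rec <- res$records
  gaps <- which(rec$source != "measured")
  for (i in gaps) {
    feas <- vapply(rs$models, function(m)
      all(!is.na(unlist(as.data.frame(trans)[i, m$inputs]))), TRUE)
    if (any(feas)) {
      expect_equal(rec$model_rank[i], min(which(feas)))
    } else {
      expect_equal(rec$source[i], "unfilled")
    }
  }
})

test_that("no gaps means verbatim output and zero model records", {
  tt <- make_tt(24, y = log(runif(24) + 1), a = rnorm(24))
  rs <- rank_models(list(make_model("a")), "all")
  res <- cascade_impute(tt, rs, "y")
  expect_equal(res$filled, exp(tt$y))
  expect_equal(sum(res$records$source == "model"), 0L)
})

test_that("traditional proxy is the rank-1 restriction; cascade never covers less", {
  f <- cascade_fixture()
  trad <- traditional_impute(f$tt, f$rs, "y")
  adap <- cascade_impute(f$tt, f$rs, "y")
  expect_true(all(is.na(trad$filled[11:20])))       # rank-1 inputs masked
  expect_equal(trad$coverage, 50 / 60)              # measured + 10 rank-1 fills
  expect_gte(mean(!is.na(adap$filled)), trad$coverage)
  # coverage is monotone in the rank cap
  cov_by_cap <- vapply(1:3, function(k)
    mean(!is.na(cascade_impute(f$tt, f$rs, "y", max_rank = k)$filled)), 0)
  expect_true(all(diff(cov_by_cap) >= 0))
})

test_that("rank usage buckets gap slots and sums to one per class", {
  rec <- data.frame(
    date = Sys.time() + 1:8, value = 1,
    source = c("measured", rep("model", 6), "unfilled"),
    model_rank = c(NA, 1, 1, 1, 2, 5, 12, NA),
    model_inputs = "x", class = "all", stringsAsFactors = FALSE)
  u <- rank_usage(rec)
  expect_equal(u$fraction[u$bucket == "1"], 3 / 7)
  expect_equal(u$fraction[u$bucket == "2"], 1 / 7)
  expect_equal(u$fraction[u$bucket == "3-10"], 1 / 7)
  expect_equal(u$fraction[u$bucket == ">10"], 1 / 7)
  expect_equal(u$fraction[u$bucket == "unfilled"], 1 / 7)
  expect_equal(sum(u$fraction), 1)
  rec2 <- rec[rec$source == "model" & rec$model_rank <= 2, ]
  u2 <- rank_usage(rec2)
  expect_equal(sum(u2$fraction), 1)
  expect_equal(u2$fraction[u2$bucket == "1"], 0.75)
  expect_equal(u2$fraction[u2$bucket == "2"], 0.25)
})

test_that("diurnal profile recovers phase and handles constants", {
  n <- 24 * 30
  dates <- as.POSIXct("2017-06-01 00:00", tz = "UTC") + 3600 * (0:(n - 1))
  hod <- as.POSIXlt(dates)$hour
  flat <- diurnal_profile(dates, rep(3.3, n))
  expect_equal(flat$mean, rep(3.3, 24))
  expect_equal(flat$sd, rep(0, 24))
  set.seed(43)
  sine <- 5 + 2 * sin(2 * pi * (hod - 8 + 6) / 24) + 0.1 * rnorm(n)
  prof <- diurnal_profile(dates, sine)   # peak at hour 8
  expect_equal(prof$hour[which.max(prof$mean)], 8)
  gappy <- replace(sine, hod == 13, NA)
  prof2 <- diurnal_profile(dates, gappy)
  expect_true(is.na(prof2$mean[prof2$hour == 13]))
  expect_equal(prof2$n[prof2$hour == 13], 0L)
})
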