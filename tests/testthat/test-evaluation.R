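test_that("R-squared matches its defining formula", {
  y <- c(0, 1, 2)
  expect_equal(r_squared(y, y), 1.0)
  expect_equal(r_squared(y, rep(mean(y), 3)), 0.0)
  expect_equal(r_squared(c(0, 1, 2), c(0, 1, 1)), 0.5)  # 1 - 1/2
  expect_error(r_squared(c(1, 1), c(0, 2)), "all equal")
})

test_that("RMSE matches its defining formula and is homogeneous", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(0, 0, 0), c(0, 0, 1)), sqrt(1 / 3))
  obs <- rnorm(20); pred <- obs + rnorm(20)
  for (c_ in c(0.5, 3)) {
    expect_equal(rmse(obs, obs + c_ * (pred - obs)),
                 abs(c_) * rmse(obs, pred))
  }
})

test_that("both Pearson forms behave as defined", {
  y <- c(0.3, 1.1, 2.7, 3.2)
  expect_equal(pearson_r(y, 2 * y + 1), 1.0)      # affine invariance
  expect_equal(pearson_r(y, -y), -1.0)
  expect_error(pearson_r(c(1, 1), c(0, 2)), "zero variance")

  # term-by-term oracle for both the standard and the covariance-only form
  obs <- c(0, 1, 2); pred <- c(0, 2, 3)
  n <- 3
  cov_oracle <- sum((pred - mean(pred)) * (obs - mean(obs))) / (n - 1)
  r_oracle <- cov_oracle / (sd(pred) * sd(obs))
  expect_equal(pearson_r_literal(obs, pred), cov_oracle)
  expect_equal(pearson_r(obs, pred), r_oracle)
  # the covariance form is not scale-bounded, the standard form is
  expect_gt(pearson_r_literal(10 * obs, 10 * pred), 1)
  expect_lte(abs(pearson_r(10 * obs, 10 * pred)), 1)
})

test_that("correlation p-values follow the t transformation", {
  expect_equal(pearson_pvalue(0, 10), 1.0)
  expect_equal(pearson_pvalue(1, 10), 0)
  expect_equal(pearson_pvalue(-1, 10), 0)
  # monotone decreasing in |r| at fixed n
  ps <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), pearson_pvalue, 0, n = 15)
  expect_true(all(diff(ps) < 0))
  # quadrature oracle: integrate the t density with n-2 dof
  r <- 0.5; n <- 20
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  tail_ <- stats::integrate(function(x) stats::dt(x, df = n - 2),
                            tstat, Inf)$value
  expect_equal(pearson_pvalue(r, n), 2 * tail_, tolerance = 1e-8)
})

test_that("all metrics match brute-force summation on random pairs", {
  set.seed(37)
  brute <- function(obs, pred) {
    n <- length(obs)
    mo <- sum(obs) / n; mp <- sum(pred) / n
    ss_res <- 0; ss_tot <- 0; sxy <- 0; sxx <- 0; syy <- 0
    for (i in seq_len(n)) {
      ss_res <- ss_res + (obs[i] - pred[i])^2
      ss_tot <- ss_tot + (obs[i] - mo)^2
      sxy <- sxy + (pred[i] - mp) * (obs[i] - mo)
      sxx <- sxx + (pred[i] - mp)^2
      syy <- syy + (obs[i] - mo)^2
    }
    list(r2 = 1 - ss_res / ss_tot, rmse = sqrt(ss_res / n),
         r = sxy / sqrt(sxx * syy), cov = sxy / (n - 1))
  }
  for (rep in 1:1000) {
    n <- sample(3:40, 1)
    obs <- rnorm(n); pred <- rnorm(n, obs, 0.5)
    o <- brute(obs, pred)
    expect_equal(r_squared(obs, pred), o$r2, tolerance = 1e-10)
    expect_equal(rmse(obs, pred), o$rmse, tolerance = 1e-10)
    expect_equal(pearson_r(obs, pred), o$r, tolerance = 1e-10)
    expect_equal(pearson_r_literal(obs, pred), o$cov, tolerance = 1e-10)
  }
})

test_that("R^2 = 1 exactly when RMSE = 0 on the same pairs", {
  set.seed(43)
  for (rep in 1:20) {
    obs <- rnorm(10)
    expect_equal(rmse(obs, obs), 0)
    expect_equal(r_squared(obs, obs), 1)
    pred <- obs + rnorm(10, 0, 0.1)
    expect_true((rmse(obs, pred) == 0) == (r_squared(obs, pred) == 1))
  }
})

test_that("stratified reports partition the records and match group-by", {
  set.seed(47)
  n <- 60
  rec <- data.frame(
    enzyme_type = sample(c("wildtype", "mutant"), n, TRUE),
    ec_number = paste0(sample(c(1:6, 7, NA), n, TRUE), ".1.1.1"))
  obs <- rnorm(n); pred <- obs + rnorm(n, 0, 0.3)
  rep_ <- stratified_report(rec, obs, pred)

  all_row <- rep_[rep_$stratum == "all", ]
  expect_equal(all_row$n, n)
  expect_equal(all_row$rmse, rmse(obs, pred))
  # wildtype + mutant partition the records
  expect_equal(sum(rep_$n[rep_$stratum %in% c("wildtype", "mutant")]), n)
  # per-stratum metrics equal a direct per-group computation
  for (ty in c("wildtype", "mutant")) {
    i <- rec$enzyme_type == ty
    expect_equal(rep_$rmse[rep_$stratum == ty], rmse(obs[i], pred[i]))
    expect_equal(rep_$pearson_r[rep_$stratum == ty],
                 pearson_r(obs[i], pred[i]))
  }
  cls <- ec_class(rec$ec_number)
  for (k in 1:6) {
    i <- which(cls == k)
    if (length(i) >= 2)
      expect_equal(rep_$rmse[rep_$stratum == paste0("EC", k)],
                   rmse(obs[i], pred[i]))
  }
  # EC classes present partition the classified records (EC7 excluded)
  ec_rows <- rep_[grepl("^EC", rep_$stratum), ]
  expect_equal(sum(ec_rows$n), sum(cls %in% 1:6))
  expect_false(any(rep_$stratum == "EC7"))
  # malformed/EC7 go to unclassified or are excluded, never fabricated
  expect_equal(rep_$n[rep_$stratum == "unclassified"], sum(is.na(cls)))
})

test_that("small strata report NA metrics instead of fabricated values", {
  rec <- data.frame(enzyme_type = rep("wildtype", 6),
                    ec_number = paste0(1:6, ".1.1.1"))
  obs <- rnorm(6); pred <- rnorm(6)
  rep_ <- stratified_report(rec, obs, pred)
  expect_equal(rep_$n[rep_$stratum == "mutant"], 0L)
  for (k in 1:6) {
    row <- rep_[rep_$stratum == paste0("EC", k), ]
    expect_equal(row$n, 1L)
    expect_true(is.na(row$r2) && is.na(row$pearson_r))
  }
})

test_that("EC classes parse from the leading digit", {
  expect_equal(ec_class(c("1.1.1.1", "6.3.1.2", "7.1.1.1")), c(1L, 6L, 7L))
  expect_true(is.na(ec_class("not-an-ec")))
  expect_true(is.na(ec_class("9.1.1.1")))
})
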