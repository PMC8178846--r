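test_that("endpoint fallback order is RFS > DMFS > DSS", {
  expect_equal(select_endpoint(c("RFS", "DMFS")), "RFS")
  expect_equal(select_endpoint(c("DSS", "DMFS")), "DMFS")
  expect_equal(select_endpoint("DSS"), "DSS")
  expect_error(select_endpoint(character(0)), "no endpoint")
  expect_error(select_endpoint("OS"), "unknown")
})

test_that("5-year truncation and landmarking respect boundary conventions", {
  cs <- cohort_survival(paste0("p", 1:5), c(80, 30, 60, 40, 100),
                        c(1, 1, 1, 1, 1))
  tr <- truncate_5y(cs)
  expect_equal(tr$time_months, c(60, 30, 60, 40, 60))
  expect_equal(tr$event, c(0L, 1L, 1L, 1L, 0L))  # event at exactly 60 kept

  lm <- landmark_late(cs)
  # kept: times strictly > 60, origin shifted; the t=60 event is excluded
  expect_equal(lm$patient_id, c("p1", "p5"))
  expect_equal(lm$time_months, c(20, 40))
  expect_equal(lm$event, c(1L, 1L))

  cens60 <- cohort_survival(paste0("q", 1:3), c(60, 70, 90), c(0, 1, 1))
  expect_equal(nrow(landmark_late(cens60)), 2L)  # censored-at-60 excluded

  few <- cohort_survival(paste0("r", 1:3), c(30, 70, 80), c(1, 0, 0))
  expect_error(landmark_late(few), "non-analyzable")
})

test_that("cox_binary matches the grid-search Efron oracle on a toy cohort", {
  # 6 patients with a tie to exercise the Efron correction
  time <- c(2, 3, 3, 5, 8, 9)
  event <- c(1, 1, 1, 0, 1, 0)
  x <- c(1, 0, 1, 1, 0, 0)
  cs <- cohort_survival(paste0("p", 1:6), time, event)
  fit <- cox_binary(cs, ifelse(x == 1, "high", "low"))
  b_oracle <- oracle_grid_max(function(b)
    oracle_efron_loglik(b, time, event, x), -3, 3)
  expect_equal(fit$log_hr, b_oracle, tolerance = 1e-6)
  expect_equal(fit$n, 6L)
  expect_equal(fit$n_events, 4L)
})

test_that("cox_binary null invariance and error contract", {
  set.seed(5)
  n <- 300
  time <- rexp(n, 0.05)
  event <- rbinom(n, 1, 0.8)
  cs <- cohort_survival(paste0("p", 1:n), time, event)
  z <- replicate(50, {
    f <- cox_binary(cs, sample(rep(c("low", "high"), n / 2)))
    f$log_hr / f$se
  })
  expect_lt(abs(mean(z)), 0.5)
  expect_gt(mean(abs(z) < 1.96), 0.85)  # ~5% type I

  noev <- cohort_survival(c("a", "b"), c(1, 2), c(0, 0))
  expect_error(cox_binary(noev, c("low", "high")), "no events")
  expect_error(cox_binary(cs, rep("low", n)), "both label groups")
  # monotone likelihood: all events in one group, perfectly separated times
  sep <- cohort_survival(paste0("s", 1:8), c(1, 2, 3, 4, 10, 11, 12, 13),
                         c(1, 1, 1, 1, 0, 0, 0, 0))
  expect_error(cox_binary(sep, rep(c("high", "low"), each = 4)),
               "converge")
})

test_that("cox_binary recovers a planted HR and is invariant to time shifts
           and patient order", {
  set.seed(6)
  n <- 2000
  x <- rbinom(n, 1, 0.5)
  time <- rexp(n, 0.02 * 0.5^x)  # HR 0.5 for x = 1, no censoring, no ties
  cs <- cohort_survival(paste0("p", 1:n), time, rep(1, n))
  lab <- ifelse(x == 1, "high", "low")
  fit <- cox_binary(cs, lab)
  expect_gt(fit$hr, 0.45); expect_lt(fit$hr, 0.56)

  shifted <- cohort_survival(cs$patient_id, cs$time_months + 7, cs$event)
  expect_equal(cox_binary(shifted, lab)$log_hr, fit$log_hr,
               tolerance = 1e-8)
  perm <- sample(n)
  permuted <- cohort_survival(cs$patient_id[perm], cs$time_months[perm],
                              cs$event[perm])
  expect_equal(cox_binary(permuted, lab[perm])$log_hr, fit$log_hr,
               tolerance = 1e-8)
})

test_that("cox_binary supports a proliferation-style adjustment covariate", {
  set.seed(8)
  n <- 500
  x <- rbinom(n, 1, 0.5)
  prolif <- rnorm(n)
  time <- rexp(n, 0.02 * exp(-0.7 * x + 0.5 * prolif))
  cs <- cohort_survival(paste0("p", 1:n), time, rep(1, n))
  fit <- cox_binary(cs, ifelse(x == 1, "high", "low"), adjustment = prolif)
  expect_equal(fit$covariates, "proliferation_score")
  expect_equal(fit$log_hr, -0.7, tolerance = 0.3)
  expect_equal(fit$adj_coef, 0.5, tolerance = 0.2)
})

mk_fit <- function(theta, se, id = "c") {
  structure(list(cohort_id = id, log_hr = theta, se = se, hr = exp(theta),
                 n = 100L, n_events = 50L, covariates = character(0),
                 adj_coef = NA_real_), class = "cox_fit")
}

test_that("meta-analysis closed forms: identical fits", {
  fits <- lapply(1:5, function(i) mk_fit(-0.7, 0.2, paste0("c", i)))
  m <- meta_analyze(fits)
  expect_equal(m$combined_log_hr, -0.7)
  expect_equal(m$combined_se, 0.2 / sqrt(5))
  expect_equal(m$Q, 0)
  expect_equal(m$model, "fixed")
  expect_equal(m$tau2, 0)
  expect_equal(m$ci95, exp(-0.7 + c(-1.96, 1.96) * 0.2 / sqrt(5)))
})

test_that("meta-analysis heterogeneous 2-study case matches the DL formulas", {
  m <- meta_analyze(list(mk_fit(0, 1, "a"), mk_fit(10, 1, "b")))
  # independent hand evaluation: w = (1,1); theta_F = 5;
  # Q = 1*(0-5)^2 + 1*(10-5)^2 = 50; tau2 = (Q - 1)/(sum w - sum w^2/sum w)
  w <- c(1, 1)
  theta <- c(0, 10)
  tf <- sum(w * theta) / sum(w)
  Q <- sum(w * (theta - tf)^2)
  tau2 <- max(0, (Q - 1) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (1 + tau2)
  expect_equal(m$Q, Q)
  expect_equal(m$Q, 50)
  expect_lt(m$q_pvalue, 1e-10)
  expect_equal(m$model, "random")
  expect_equal(m$tau2, tau2)
  expect_equal(m$tau2, 49)
  expect_equal(m$combined_log_hr, sum(ws * theta) / (2 * ws))  # = 5
  expect_equal(m$combined_se, 1 / sqrt(2 * ws))                # = 5
})

test_that("meta-analysis invariants and input validation", {
  set.seed(9)
  for (r in 1:20) {
    fits <- lapply(1:6, function(i)
      mk_fit(rnorm(1, -0.5, 0.6), runif(1, 0.1, 0.5), paste0("c", i)))
    m <- meta_analyze(fits)
    th <- vapply(fits, function(f) f$log_hr, 0)
    expect_gte(m$combined_log_hr, min(th))
    expect_lte(m$combined_log_hr, max(th))
    # random-effects se >= fixed se on the same fits
    fixed_se <- 1 / sqrt(sum(1 / vapply(fits, function(f) f$se, 0)^2))
    expect_gte(m$combined_se, fixed_se - 1e-12)
    if (m$model == "fixed") expect_equal(m$tau2, 0)
  }
  expect_error(meta_analyze(list(mk_fit(0, 1))), "at least 2")
  expect_error(meta_analyze(list(mk_fit(0, 1), mk_fit(0, -1))), "positive")
})
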