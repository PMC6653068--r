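test_that("design matrices carry the documented row and parameter counts", {
  cfg <- sim_config(visits_min = 8, visits_max = 8, seed = 2)
  z <- z_normalize(simulate_cohort(cfg)$cohort)

  da <- build_design(z, "time_agnostic")
  expect_equal(nrow(da$x), 110 * 8)
  expect_equal(ncol(da$x), 18)  # 17 coefficients + intercept

  dd <- build_design(z, "time_dependent")
  expect_equal(nrow(dd$x), 110 * 7)  # first visit dropped per patient
  expect_equal(ncol(dd$x), 35)       # 34 coefficients + intercept

  expect_error(build_design(simulate_cohort(cfg)$cohort, "time_agnostic"),
               "normalized")
})

test_that("lagged columns are the same patient's prior visit", {
  co <- make_linear_cohort(n_pat = 1, n_vis = 3)
  d <- suppressMessages(build_design(co, "time_dependent"))
  expect_equal(nrow(d$x), 2)
  vals <- as.matrix(co$visits[, parameter_panel()])
  expect_equal(unname(d$x[, paste0("lag_", parameter_panel())]),
               unname(vals[1:2, ]))
  expect_equal(unname(d$x[, parameter_panel()]), unname(vals[2:3, ]))
  # never lag across patients
  co2 <- make_linear_cohort(n_pat = 3, n_vis = 3)
  d2 <- build_design(co2, "time_dependent")
  expect_equal(nrow(d2$x), 6)
  expect_equal(unique(table(d2$row_key$patient_id)), 2L)
})

test_that("OLS is exact on noiseless data and matches normal equations", {
  co <- make_linear_cohort()
  fit <- fit_linear(build_design(co, "time_agnostic"))
  expect_lt(max(abs(fit$residuals)), 1e-10)

  set.seed(30)
  for (rep in 1:10) {
    X <- cbind(1, matrix(rnorm(20 * 5), 20, 5))
    colnames(X) <- c("(Intercept)", paste0("v", 1:5))
    y <- rnorm(20)
    got <- fit_linear(list(x = X, y = y))$coefficients
    expect_lt(max(abs(got - ols_oracle(X, y))), 1e-8)
  }

  # Monte-Carlo consistency: response = 2 x1 + 3 + noise-only predictors
  set.seed(31)
  X <- cbind("(Intercept)" = 1, x1 = rnorm(1000),
             x2 = rnorm(1000), x3 = rnorm(1000))
  y <- 2 * X[, "x1"] + 3 + rnorm(1000, 0, 0.5)
  cf <- fit_linear(list(x = X, y = y))$coefficients
  expect_gt(cf["x1"], 1.9); expect_lt(cf["x1"], 2.1)
  expect_gt(cf["(Intercept)"], 2.8); expect_lt(cf["(Intercept)"], 3.2)

  Xdup <- cbind(X, x1_copy = X[, "x1"])
  expect_error(fit_linear(list(x = Xdup, y = y)), "x1_copy")
})

test_that("LOPO predictions generalize an exact linear model", {
  co <- make_linear_cohort(n_pat = 10, n_vis = 4)
  pred <- lopo_cv(co, "time_agnostic")
  expect_lt(max(abs(pred$residual)), 1e-8)
  expect_equal(nrow(pred), nrow(build_design(co, "time_agnostic")$x))

  lag_co <- make_linear_cohort(n_pat = 12, n_vis = 5, lagged = TRUE)
  predl <- lopo_cv(lag_co, "time_dependent")
  expect_lt(max(abs(predl$residual)), 1e-8)
})

test_that("LOPO folds equal per-fold normal-equations fits", {
  set.seed(44)
  rows <- list()
  for (p in 1:3) {
    vals <- matrix(rnorm(4 * 17), 4, 17)
    colnames(vals) <- parameter_panel()
    rows[[p]] <- data.frame(patient_id = sprintf("H%d", p), day = 0:3,
                            sledai = sample(0:10, 4, TRUE), vals,
                            check.names = FALSE)
  }
  co <- sle_cohort(do.call(rbind, rows))
  co$normalized <- TRUE
  # 3 patients x 4 visits = 12 rows cannot support 18 columns; use a reduced
  # panel via direct design manipulation instead: check fold mechanics on the
  # first 5 parameters only
  d <- build_design(co, "time_agnostic")
  d$x <- d$x[, 1:6]
  for (p in sprintf("H%d", 1:3)) {
    test <- d$row_key$patient_id == p
    beta <- ols_oracle(d$x[!test, ], d$y[!test])
    manual <- as.vector(d$x[test, ] %*% beta)
    fit <- fit_linear(list(x = d$x[!test, ], y = d$y[!test]))
    auto <- as.vector(d$x[test, ] %*% fit$coefficients)
    expect_lt(max(abs(manual - auto)), 1e-8)
  }
})

test_that("error summaries are mean-square and mean-absolute residuals", {
  expect_equal(error_summary(data.frame(residual = c(1, -1))),
               list(mean_square = 1, mean_absolute = 1, n = 2L))
  expect_equal(error_summary(data.frame(residual = c(0, 0)))$mean_square, 0)
  es <- error_summary(data.frame(residual = c(3, -4)))
  expect_equal(es$mean_square, 12.5)
  expect_equal(es$mean_absolute, 3.5)
  expect_error(error_summary(data.frame(residual = numeric(0))), "empty")
})

test_that("the patient-level bootstrap is seeded and unbiased", {
  co <- make_linear_cohort(n_pat = 10, n_vis = 4)
  s <- bootstrap_error(co, "time_agnostic", n_iter = 50, seed = 5)
  expect_true(all(s < 1e-8))
  s2 <- bootstrap_error(co, "time_agnostic", n_iter = 50, seed = 5)
  expect_identical(as.vector(s), as.vector(s2))

  # known-noise recovery: with iid N(0, sigma^2) noise and Gaussian
  # predictors, the expected out-of-sample MSE of OLS is about
  # sigma^2 (1 + k / (n_train - k - 1)); averaged over independent cohorts
  # (a single cohort's conditional error fluctuates around this)
  set.seed(46)
  sigma <- 2
  make_noisy <- function() {
    rows <- lapply(1:120, function(p) {
      vals <- matrix(rnorm(3 * 17), 3, 17)
      colnames(vals) <- parameter_panel()
      data.frame(patient_id = sprintf("N%03d", p), day = 0:2,
                 sledai = as.vector(5 + vals %*% rep(0.5, 17) +
                                      rnorm(3, 0, sigma)),
                 vals, check.names = FALSE)
    })
    co <- sle_cohort(do.call(rbind, rows))
    co$normalized <- TRUE
    co
  }
  cohort_means <- vapply(1:8, function(i) {
    mean(bootstrap_error(make_noisy(), "time_agnostic", n_iter = 60,
                         seed = i))
  }, numeric(1))
  n_train <- 0.8 * 120 * 3
  expected <- sigma^2 * (1 + 18 / (n_train - 19))
  se <- sd(cohort_means) / sqrt(length(cohort_means))
  expect_lt(abs(mean(cohort_means) - expected), 4 * se)
})

test_that("paired bootstrap comparison reports differences and a floor p", {
  s <- c(1, 2, 3, 4)
  same <- compare_models(s, s)
  expect_equal(same$mean_diff, 0)
  expect_equal(same$p, 1)

  shift <- compare_models(s, s - 1)
  expect_equal(shift$mean_diff, 1)
  expect_gt(shift$ci_low, 0)
  expect_equal(shift$p, 1 / 4)  # continuity floor at 1/n_iter

  expect_error(compare_models(s, s[-1]), "equal length")
})
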