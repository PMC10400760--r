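test_that("age acceleration residuals are exact OLS residuals, orthogonal to age", {
  age <- c(45, 52, 60, 71, 88)
  # linear maps of age are absorbed completely
  expect_equal(compute_age_accel(age, age)$accel, rep(0, 5))
  expect_equal(compute_age_accel(2 * age + 7, age)$accel, rep(0, 5))

  dnam <- c(47, 50, 66, 70, 85)
  acc <- compute_age_accel(dnam, age)$accel
  A <- cbind(1, age)
  resid_oracle <- dnam - A %*% solve(t(A) %*% A, t(A) %*% dnam)
  expect_equal(acc, as.numeric(resid_oracle), tolerance = 1e-10)
  expect_lt(abs(cor(acc, age)), 1e-10)
  expect_lt(abs(mean(acc)), 1e-10)
  expect_error(compute_age_accel(dnam, rep(50, 5)), "constant")
})

test_that("acceleration orthogonality holds on simulated clock output", {
  co <- small_cohort()
  model <- train_clock(co$beta[1:100, ], co$samples, nlambda = 30)
  pred <- predict_age(model, co$beta[1:100, ])
  acc <- compute_age_accel(pred$dnam_age, co$samples$age,
                          co$samples$sample_id)
  expect_lt(abs(cor(acc$accel, co$samples$age)), 1e-10)
})

test_that("Cox fit maximizes the Breslow partial likelihood (brute-force oracle)", {
  time <- 1:8
  event <- rep(c(1, 0), 4)
  x <- c(1, 0, 0, 1, 1, 0, 1, 0)
  fit <- fit_cox(time, event, cbind(x = x))
  # explicit partial likelihood over a fine grid
  logpl <- function(b) {
    sum(vapply(which(event == 1), function(i) {
      rs <- which(time >= time[i])
      x[i] * b - log(sum(exp(x[rs] * b)))
    }, numeric(1)))
  }
  grid <- seq(-5, 5, by = 1e-4)
  b_star <- grid[which.max(vapply(grid, logpl, numeric(1)))]
  expect_equal(fit$coefficients$log_hr, b_star, tolerance = 1e-3)
  expect_equal(fit$loglik, logpl(fit$coefficients$log_hr), tolerance = 1e-8)
})

test_that("Cox fit agrees with survival::coxph under Breslow ties", {
  skip_if_not_installed("survival")
  set.seed(12)
  n <- 300
  x1 <- rnorm(n); x2 <- rbinom(n, 1, 0.4)
  time <- ceiling(rexp(n, exp(0.3 * x1 - 0.5 * x2) / 20))  # integer ties
  event <- as.integer(time <= 15)
  time <- pmin(time, 15)
  fit <- fit_cox(time, event, cbind(x1 = x1, x2 = x2))
  cp <- survival::coxph(survival::Surv(time, event) ~ x1 + x2,
                        ties = "breslow")
  expect_equal(fit$coefficients$log_hr, unname(coef(cp)), tolerance = 1e-6)
  expect_equal(fit$coefficients$se,
               unname(sqrt(diag(vcov(cp)))), tolerance = 1e-6)
})

test_that("Cox estimate is invariant to time-unit rescaling and flags degeneracies", {
  set.seed(13)
  x <- rnorm(100)
  sv <- simulate_survival(x, 0.05, 1.3, 20, seed = 2L)
  f_years <- fit_cox(sv$time, sv$event, cbind(x = x))
  f_days <- fit_cox(sv$time * 365.25, sv$event, cbind(x = x))
  expect_equal(f_years$coefficients$log_hr, f_days$coefficients$log_hr,
               tolerance = 1e-8)
  # constant covariate: no discrimination, log HR exactly 0 (SE undefined)
  expect_warning(f_const <- fit_cox(sv$time, sv$event, cbind(x = rep(1, 100))),
                 "singular")
  expect_equal(f_const$coefficients$log_hr, 0)
  expect_true(is.na(f_const$coefficients$se))
  expect_error(fit_cox(sv$time, rep(0, 100), cbind(x = x)), "event")
})

test_that("fixed-effect meta-analysis follows the inverse-variance formulas", {
  one <- meta_fixed_effect(0.3, 0.12)
  expect_equal(one$estimate, 0.3)
  expect_equal(one$se, 0.12)
  two <- meta_fixed_effect(c(0.4, 0.4), c(0.1, 0.1))
  expect_equal(two$estimate, 0.4)
  expect_equal(two$se, 0.1 / sqrt(2))
  hand <- meta_fixed_effect(c(0.5, 0.1), c(0.1, 0.2))
  expect_equal(hand$estimate, 0.42, tolerance = 1e-12)
  expect_equal(hand$se, 1 / sqrt(125), tolerance = 1e-12)
  expect_error(meta_fixed_effect(0.2, 0), "> 0")
  # combined SE strictly decreases as strata accumulate
  ses <- c(0.2, 0.3, 0.15)
  for (k in 2:3) {
    expect_lt(meta_fixed_effect(rep(0.1, k), ses[1:k])$se,
              meta_fixed_effect(rep(0.1, k - 1), ses[1:(k - 1)])$se)
  }
})

test_that("meta-analysis agrees with metafor's fixed-effect model", {
  skip_if_not_installed("metafor")
  est <- c(0.31, -0.05, 0.18, 0.09)
  se <- c(0.11, 0.25, 0.08, 0.3)
  mine <- meta_fixed_effect(est, se)
  ref <- metafor::rma(yi = est, sei = se, method = "FE")
  expect_equal(mine$estimate, as.numeric(ref$beta), tolerance = 1e-10)
  expect_equal(mine$se, as.numeric(ref$se), tolerance = 1e-10)
})

test_that("biweight midcorrelation is exact on affine maps and robust to outliers", {
  set.seed(14)
  x <- rnorm(30)
  expect_equal(bicor(x, x), 1, tolerance = 1e-12)
  expect_equal(bicor(x, -3 * x + 2), -1, tolerance = 1e-12)
  expect_equal(bicor(x, 2 * x + 5), bicor(2 * x + 5, x), tolerance = 1e-12)

  # 9-point fixture with one gross outlier vs an independently coded oracle
  x9 <- c(1.2, 2.1, 2.9, 4.2, 5.1, 5.8, 7.1, 8.2, 30)
  y9 <- c(2.0, 2.4, 3.1, 3.9, 5.3, 5.9, 6.8, 8.4, -10)
  oracle <- function(a, b) {
    num <- 0; da2 <- 0; db2 <- 0
    med_a <- sort(a)[5]; med_b <- sort(b)[5]
    mad_a <- sort(abs(a - med_a))[5]; mad_b <- sort(abs(b - med_b))[5]
    wa <- numeric(9); wb <- numeric(9)
    for (i in 1:9) {
      u <- (a[i] - med_a) / (9 * mad_a)
      v <- (b[i] - med_b) / (9 * mad_b)
      wa[i] <- if (abs(u) < 1) (1 - u^2)^2 else 0
      wb[i] <- if (abs(v) < 1) (1 - v^2)^2 else 0
    }
    for (i in 1:9) {
      num <- num + (a[i] - med_a) * wa[i] * (b[i] - med_b) * wb[i]
      da2 <- da2 + ((a[i] - med_a) * wa[i])^2
      db2 <- db2 + ((b[i] - med_b) * wb[i])^2
    }
    num / sqrt(da2 * db2)
  }
  expect_equal(bicor(x9, y9), oracle(x9, y9), tolerance = 1e-8)
  # the outlier drags Pearson negative; bicor stays with the bulk trend
  expect_lt(cor(x9, y9), 0)
  expect_gt(bicor(x9, y9), 0.7)
  # dropping the outlier pair shows the bulk trend bicor tracks
  expect_gt(cor(x9[1:8], y9[1:8]), 0.99)
  expect_warning(b0 <- bicor(c(rep(1, 8), 2, 3), c(1:10)), "MAD")
  expect_equal(b0, cor(c(rep(1, 8), 2, 3), 1:10))
})

test_that("stratified bicor meta recovers planted signs and gains precision", {
  set.seed(15)
  accel <- rnorm(1000, 0, 3)
  bm <- simulate_biomarkers(accel, targets = c(-0.17, 0.09), seed = 3L)
  df <- dplyr::bind_cols(tibble::tibble(accel = accel,
                                        cohort = rep(c("a", "b"), 500)), bm)
  tab <- stratified_bicor_meta(df, "accel",
                               c("biomarker_01", "biomarker_02"), "cohort")
  expect_equal(tab$stratum_count, c(2L, 2L))

  # single stratum: meta estimate equals the plain bicor (via Fisher z)
  df1 <- df[df$cohort == "a", ]
  t1 <- stratified_bicor_meta(df1, "accel", "biomarker_01", "cohort")
  expect_equal(t1$meta_bicor, bicor(df1$accel, df1$biomarker_01),
               tolerance = 1e-10)

  # duplicated stratum: same estimate, smaller p than one stratum alone
  df2 <- df1; df2$cohort <- "b"
  t2 <- stratified_bicor_meta(dplyr::bind_rows(df1, df2), "accel",
                              "biomarker_01", "cohort")
  expect_equal(t2$meta_bicor, t1$meta_bicor, tolerance = 1e-10)
  expect_lt(t2$p, t1$p)

  # sign recovery across 20 seeded replicates
  hits <- vapply(1:20, function(s) {
    acc <- rnorm(1000, 0, 3)
    b <- simulate_biomarkers(acc, targets = c(-0.17, 0, 0.09), seed = s)
    d <- dplyr::bind_cols(tibble::tibble(accel = acc,
                                         cohort = rep(c("a", "b"), 500)), b)
    tt <- stratified_bicor_meta(d, "accel", c("biomarker_01", "biomarker_03"),
                                "cohort")
    c(tt$meta_bicor[1] < 0, tt$meta_bicor[2] > 0)
  }, logical(2))
  expect_gte(mean(hits[1, ]), 0.95)
  expect_gte(mean(hits[2, ]), 0.95)
})

test_that("stratified mortality meta combines per-cohort Cox fits", {
  co <- default_cohort()
  df <- co$samples
  df$accel <- df$true_accel
  tab <- mortality_meta(df, "accel", covariates = c("age", "sex"),
                        strata = "cohort")
  expect_equal(tab$stratum[nrow(tab)], "meta")
  k <- nrow(tab) - 1
  meta_oracle <- meta_fixed_effect(tab$log_hr[1:k], tab$se[1:k])
  expect_equal(tab$log_hr[k + 1], meta_oracle$estimate, tolerance = 1e-12)
  expect_lte(tab$se[k + 1], min(tab$se[1:k]))
  expect_gte(tab$log_hr[k + 1], min(tab$log_hr[1:k]))
  expect_lte(tab$log_hr[k + 1], max(tab$log_hr[1:k]))
})
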