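test_that("centenarian weighting is boundary-inclusive at exactly 100", {
  expect_equal(sample_weights(c(50, 99.9, 100, 110), 10), c(1, 1, 10, 10))
  expect_equal(sample_weights(c(50, 120), 1), c(1, 1))
  expect_error(sample_weights(c(-1, 50)), "non-negative")
  expect_error(sample_weights(50, centenarian_weight = 0.5), ">= 1")
})

test_that("the neural net is seed-deterministic and can overfit a linear toy", {
  set.seed(4)
  X <- matrix(rnorm(20 * 3), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- 60 + 8 * X[, 1]
  f1 <- fit_mlp(X, y, epochs = 800, seed = 5L)
  f2 <- fit_mlp(X, y, epochs = 800, seed = 5L)
  expect_identical(f1$layers, f2$layers)
  expect_lt(mean(abs(predict(f1, X) - y)), 1)
  # different seed, different weights
  f3 <- fit_mlp(X, y, epochs = 10, seed = 6L)
  expect_false(identical(f1$layers[[1]]$W, f3$layers[[1]]$W))
})

test_that("a zero-hidden-layer network converges to the least-squares fit", {
  set.seed(8)
  X <- matrix(rnorm(50 * 2), 50, 2, dimnames = list(NULL, c("a", "b")))
  y <- 70 + 2 * X[, 1] - 3 * X[, 2] + rnorm(50, 0, 0.5)
  f <- fit_mlp(X, y, hidden_sizes = integer(0), epochs = 3000,
               learning_rate = 0.02, seed = 1L)
  ls <- lm.fit(cbind(1, X), y)
  expect_equal(unname(predict(f, X)), unname(ls$fitted.values),
               tolerance = 0.02)
})

test_that("prediction handles degenerate models, extra rows, and missing CpGs", {
  co <- small_cohort()
  beta <- co$beta[1:50, ]
  model <- train_clock(beta, co$samples, lambda = 1e6)  # full shrinkage
  pred <- predict_age(model, beta)
  expect_equal(length(unique(round(pred$dnam_age, 10))), 1)  # constant intercept
  # weighted mean of training ages
  w <- sample_weights(co$samples$age)
  expect_equal(pred$dnam_age[1], weighted.mean(co$samples$age, w),
               tolerance = 1e-8)

  model2 <- train_clock(beta, co$samples, nlambda = 30)
  p_all <- predict_age(model2, co$beta)   # extra CpG rows are ignored
  p_sub <- predict_age(model2, beta)
  expect_equal(p_all$dnam_age, p_sub$dnam_age)
  used <- names(model2$coefficients)
  expect_error(predict_age(model2, beta[setdiff(rownames(beta), used[1]), ]),
               "required CpG")
})

test_that("unpenalized training predictions reproduce the least-squares oracle", {
  co <- small_cohort()
  beta <- co$beta[1:8, ]  # p << n so lambda = 0 is well-posed
  model <- train_clock(beta, co$samples, lambda = 0, centenarian_weight = 10)
  pred <- predict_age(model, beta)
  w <- sample_weights(co$samples$age, 10)
  A <- cbind(1, t(beta))
  cf <- solve(t(A) %*% (w * A), t(A) %*% (w * co$samples$age))
  expect_equal(pred$dnam_age, as.numeric(A %*% cf), tolerance = 1e-5)
})

test_that("clock serialization round-trips predictions exactly", {
  co <- small_cohort()
  beta <- co$beta[1:60, ]
  dir <- withr::local_tempdir()
  for (kind in c("elastic_net", "neural_net")) {
    model <- train_clock(beta, co$samples, kind = kind, nlambda = 20,
                         epochs = 50, seed = 2L)
    write_clock(model, file.path(dir, kind))
    back <- read_clock(file.path(dir, kind))
    expect_equal(predict_age(back, beta)$dnam_age,
                 predict_age(model, beta)$dnam_age, tolerance = 1e-12)
  }
})

test_that("20-fold cross-validation partitions evenly and is honest about folds", {
  co <- small_cohort()
  beta <- co$beta[1:40, 1:40]
  sheet <- co$samples[1:40, ]
  builder <- function(b, s) train_clock(b, s, lambda = 0.5)
  cv <- crossvalidate_20fold(beta, sheet, builder, n_folds = 20, seed = 3L)
  expect_equal(unname(table(cv$fold_assignment)), rep(2L, 20),
               ignore_attr = TRUE)
  expect_false(anyNA(cv$oof$dnam_age))

  # fully shrunk builder: every fold predicts its training mean, so the oof
  # MAE is exactly the MAE of those constants
  const_builder <- function(b, s) train_clock(b, s, lambda = 1e6)
  cvc <- crossvalidate_20fold(beta, sheet, const_builder, n_folds = 20,
                              seed = 3L, strata = age_strata("40plus"))
  expect_equal(cvc$metrics$mae_years[1],
               median(abs(cvc$oof$dnam_age - sheet$age)))
  # a single constant prediction vector leaves r undefined
  m_const <- stratified_metrics(rep(70, 40), sheet$age, age_strata("40plus"))
  expect_true(is.na(m_const$pearson_r[1]))
})

test_that("stratified metrics match direct arithmetic", {
  strata <- age_strata()
  perfect <- stratified_metrics(c(50, 60, 80, 101), c(50, 60, 80, 101), strata)
  expect_equal(perfect$mae_years[1], 0)
  expect_equal(perfect$pearson_r[1], 1)
  shifted <- stratified_metrics(c(55, 65, 85, 106), c(50, 60, 80, 101), strata)
  expect_equal(shifted$mae_years, c(5, 5, 5), ignore_attr = TRUE)
  expect_equal(shifted$pearson_r[1], 1)
  expect_true(is.na(shifted$pearson_r[3]))  # one centenarian: r undefined

  # 6-point hand fixture vs textbook formulas
  pred <- c(48, 62, 57, 75, 92, 103)
  age <- c(45, 60, 61, 70, 85, 100)
  m <- stratified_metrics(pred, age, age_strata("40plus"))
  expect_equal(m$n, 6L)
  expect_equal(m$mae_years, median(abs(pred - age)))
  r_hand <- sum((pred - mean(pred)) * (age - mean(age))) /
    sqrt(sum((pred - mean(pred))^2) * sum((age - mean(age))^2))
  expect_equal(m$pearson_r, r_hand, tolerance = 1e-12)
})

test_that("tidy and glance expose the fitted clock", {
  co <- small_cohort()
  model <- train_clock(co$beta[1:50, ], co$samples, nlambda = 20)
  td <- tidy(model)
  expect_equal(td$term[1], "(Intercept)")
  expect_equal(nrow(td), length(model$coefficients) + 1)
  gl <- glance(model)
  expect_equal(gl$kind, "elastic_net")
  expect_equal(gl$centenarian_weight, 10)
})
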