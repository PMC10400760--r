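# Centenarian-weighted age clocks: training, prediction, 20-fold
# cross-validation, age-stratified metrics, and a portable serialized form.

#' Per-sample regression weights with up-weighted centenarians
#'
#' Samples aged 100 or older (boundary inclusive) receive
#' `centenarian_weight`; everyone else weight 1. Up-weighting the rare 100+
#' tail is what keeps the clock calibrated in the oldest old.
#'
#' @param ages Ages in years (>= 0).
#' @param centenarian_weight Multiplier (>= 1) for samples aged >= 100.
#' @param threshold Age boundary in years (default 100).
#' @return Numeric weight vector.
#' @export
#' @examples
#' sample_weights(c(50, 99.9, 100, 110), 10)
sample_weights <- function(ages, centenarian_weight = 10, threshold = 100) {
  stop_if(any(ages < 0), "ages must be non-negative")
  stop_if(centenarian_weight < 1, "centenarian_weight must be >= 1")
  ifelse(ages >= threshold, centenarian_weight, 1)
}

#' Age strata used when reporting clock performance
#'
#' @param labels Which of the standard strata to include.
#' @return A tibble `label`, `min_age`, `max_age` (bounds inclusive).
#' @export
age_strata <- function(labels = c("40plus", "80plus", "100plus")) {
  all <- tibble::tibble(
    label = c("40plus", "80plus", "100plus"),
    min_age = c(40, 80, 100),
    max_age = c(Inf, Inf, Inf)
  )
  dplyr::filter(all, .data$label %in% labels)
}

#' Train a methylation age clock
#'
#' Fits either a centenarian-weighted elastic net (mixing `alpha = 0.5`,
#' lambda chosen by cross-validation on the training data) or a fixed
#' architecture ReLU neural network on samples inside the training age
#' window. Samples aged >= 100 get weight `centenarian_weight` in the loss.
#'
#' @param beta CpG x sample beta matrix (features should normally come from
#'   [prefilter_cpgs()]).
#' @param sheet Sample sheet with `sample_id` and `age`.
#' @param kind `"elastic_net"` or `"neural_net"`.
#' @param train_age_min,train_age_max Training age window in years (bounds
#'   inclusive).
#' @param centenarian_weight Weight multiplier for samples aged >= 100.
#' @param alpha Elastic-net mixing parameter.
#' @param lambda Optional fixed lambda (skips cross-validated selection).
#' @param nlambda Path length for the lambda grid.
#' @param cv_folds Folds for lambda selection.
#' @param hidden_sizes,epochs,learning_rate Neural-network settings (fixed a
#'   priori, not tuned per dataset).
#' @param seed Integer seed (fold assignment, network initialization).
#' @return An object of class `clock_model`.
#' @export
train_clock <- function(beta, sheet, kind = c("elastic_net", "neural_net"),
                        train_age_min = 40, train_age_max = Inf,
                        centenarian_weight = 10, alpha = 0.5, lambda = NULL,
                        nlambda = 100, cv_folds = 10,
                        hidden_sizes = c(64L, 32L), epochs = 600,
                        learning_rate = 0.01, seed = 1L) {
  kind <- match.arg(kind)
  check_beta_matrix(beta)
  sheet <- align_sheet_to_beta(beta, check_sample_sheet(sheet))
  keep <- sheet$age >= train_age_min & sheet$age <= train_age_max
  stop_if(sum(keep) < 3, "fewer than 3 samples in the training age window")
  X <- t(impute_beta(beta[, keep, drop = FALSE]))
  y <- sheet$age[keep]
  w <- sample_weights(y, centenarian_weight)
  # constant features carry no signal and break standardization
  keep_feat <- apply(X, 2, function(col) var(col) > 0)
  X <- X[, keep_feat, drop = FALSE]
  stop_if(ncol(X) == 0, "no non-constant features in the training window")

  if (kind == "elastic_net") {
    path <- fit_weighted_elastic_net(X, y, w, alpha, lambda = lambda,
                                     nlambda = nlambda)
    if (is.null(lambda) && length(path$lambda) > 1) {
      cv <- select_lambda_cv(X, y, w, alpha, lambda = path$lambda,
                             n_folds = cv_folds, seed = seed)
      s <- which(path$lambda == cv$lambda)[1]
      cv_tab <- cv$cv
    } else {
      s <- length(path$lambda)
      cv_tab <- NULL
    }
    coefs <- path$beta[, s]
    coefs <- coefs[coefs != 0]
    model <- list(kind = kind, intercept = path$a0[s], coefficients = coefs,
                  alpha = alpha, lambda = path$lambda[s],
                  feature_means = path$feature_means[names(coefs)],
                  feature_sds = path$feature_sds[names(coefs)],
                  cv = cv_tab, fit = NULL)
  } else {
    fit <- fit_mlp(X, y, w, hidden_sizes = hidden_sizes, epochs = epochs,
                   learning_rate = learning_rate, seed = seed)
    model <- list(kind = kind, intercept = NA_real_, coefficients = NULL,
                  alpha = NA_real_, lambda = NA_real_,
                  feature_means = fit$feature_means,
                  feature_sds = fit$feature_sds, cv = NULL, fit = fit)
  }
  model$training_age_min <- train_age_min
  model$training_age_max <- train_age_max
  model$centenarian_weight <- centenarian_weight
  model$n_train <- sum(keep)
  model$seed <- as.integer(seed)
  structure(model, class = "clock_model")
}

#' @export
print.clock_model <- function(x, ...) {
  nf <- if (x$kind == "elastic_net") length(x$coefficients) else
    length(x$feature_means)
  cat(sprintf("<clock_model> %s, trained on %d samples aged %s-%s, %d features\n",
              x$kind, x$n_train, format(x$training_age_min),
              format(x$training_age_max), nf))
  invisible(x)
}

#' Predict DNA methylation age
#'
#' @param model A `clock_model`.
#' @param beta CpG x sample beta matrix containing every CpG the model uses
#'   (extra rows are ignored; missing ones are an error).
#' @return A tibble `sample_id`, `dnam_age` (years).
#' @export
predict_age <- function(model, beta) {
  stop_if(!inherits(model, "clock_model"), "`model` must be a clock_model")
  needed <- if (model$kind == "elastic_net") names(model$coefficients) else
    model$fit$feature_names
  missing <- setdiff(needed, rownames(beta))
  stop_if(length(missing) > 0,
          paste0("beta matrix lacks ", length(missing), " required CpG(s), e.g. ",
                 missing[1]))
  X <- t(impute_beta(beta[needed, , drop = FALSE]))
  stop_if(anyNA(X), "NaN feature values after imputation")
  pred <- if (model$kind == "elastic_net") {
    as.numeric(X %*% model$coefficients) + model$intercept
  } else {
    as.numeric(predict(model$fit, X))
  }
  tibble::tibble(sample_id = colnames(beta), dnam_age = pred)
}

#' 20-fold cross-validation of a clock builder
#'
#' Randomly partitions samples into `n_folds` near-equal bins (seeded); each
#' model is trained on the other bins and evaluated on the left-out bin, so
#' every sample's prediction is out-of-fold. Metrics are reported per age
#' stratum.
#'
#' @param beta CpG x sample beta matrix.
#' @param sheet Sample sheet with `sample_id` and `age`.
#' @param builder Function `(beta, sheet) -> clock_model`; default trains the
#'   centenarian-weighted elastic net via [train_clock()].
#' @param n_folds Number of folds (default 20).
#' @param seed Integer seed for the partition.
#' @param strata Strata tibble from [age_strata()].
#' @return An object of class `cv_result`: `oof` (tibble `sample_id`, `age`,
#'   `dnam_age`, `fold`), `metrics` (per-stratum tibble), `fold_assignment`.
#' @export
crossvalidate_20fold <- function(beta, sheet, builder = NULL, n_folds = 20,
                                 seed = 1L, strata = age_strata()) {
  check_beta_matrix(beta)
  sheet <- align_sheet_to_beta(beta, check_sample_sheet(sheet))
  stop_if(ncol(beta) < n_folds, "need at least one sample per fold")
  builder <- builder %||% function(b, s)
    train_clock(b, s, kind = "elastic_net", train_age_min = 0, seed = seed)
  folds <- assign_folds(ncol(beta), n_folds, seed)
  oof <- rep(NA_real_, ncol(beta))
  for (k in seq_len(n_folds)) {
    tr <- folds != k
    model <- builder(beta[, tr, drop = FALSE], sheet[tr, , drop = FALSE])
    oof[!tr] <- predict_age(model, beta[, !tr, drop = FALSE])$dnam_age
  }
  oof_tab <- tibble::tibble(sample_id = sheet$sample_id, age = sheet$age,
                            dnam_age = oof, fold = folds)
  metrics <- stratified_metrics(oof, sheet$age, strata)
  structure(list(oof = oof_tab, metrics = metrics,
                 fold_assignment = setNames(folds, sheet$sample_id),
                 n_folds = n_folds, seed = as.integer(seed)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d-fold out-of-fold predictions for %d samples\n",
              x$n_folds, nrow(x$oof)))
  print(x$metrics)
  invisible(x)
}

#' Clock accuracy per age stratum
#'
#' For each stratum: sample count, Pearson correlation between predicted and
#' chronological age, and the median absolute error in years. Strata with
#' fewer than 3 samples (or degenerate variance) report `NA` correlations
#' rather than erroring.
#'
#' @param pred Predicted ages (years).
#' @param age Chronological ages (years).
#' @param strata Strata tibble from [age_strata()] (bounds inclusive).
#' @return A tibble `label`, `n`, `pearson_r`, `mae_years`.
#' @export
stratified_metrics <- function(pred, age, strata = age_strata()) {
  stop_if(length(pred) != length(age), "pred and age must have equal length")
  purrr::pmap(strata, function(label, min_age, max_age) {
    idx <- which(age >= min_age & age <= max_age & !is.na(pred))
    r <- if (length(idx) >= 3 && sd(age[idx]) > 0 && sd(pred[idx]) > 0)
      cor(pred[idx], age[idx]) else NA_real_
    mae <- if (length(idx) > 0) median(abs(pred[idx] - age[idx])) else NA_real_
    tibble::tibble(label = label, n = length(idx), pearson_r = r,
                   mae_years = mae)
  }) %>% dplyr::bind_rows()
}

#' @export
tidy.clock_model <- function(x, ...) {
  if (x$kind == "elastic_net") {
    tibble::tibble(term = c("(Intercept)", names(x$coefficients)),
                   estimate = c(x$intercept, unname(x$coefficients)))
  } else {
    purrr::imap(x$fit$layers, function(l, i)
      tibble::tibble(term = sprintf("layer%d", i),
                     n_weights = length(l$W) + length(l$b))) %>%
      dplyr::bind_rows()
  }
}

#' @export
glance.clock_model <- function(x, ...) {
  tibble::tibble(kind = x$kind, n_train = x$n_train,
                 n_features = if (x$kind == "elastic_net")
                   length(x$coefficients) else length(x$feature_means),
                 alpha = x$alpha, lambda = x$lambda,
                 training_age_min = x$training_age_min,
                 training_age_max = x$training_age_max,
                 centenarian_weight = x$centenarian_weight, seed = x$seed)
}

#' Serialize a clock to a directory (JSON metadata + CSV/JSON weights)
#'
#' Elastic-net clocks write `coefficients.csv` (`cpg_id,weight`, first row
#' `__intercept__`); neural-net clocks write their layer weights as flat JSON
#' arrays. Metadata (kind, alpha, lambda, seed, training window,
#' centenarian weight, standardization constants) goes to `clock.json`.
#'
#' @param model A `clock_model`.
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_clock <- function(model, dir) {
  stop_if(!inherits(model, "clock_model"), "`model` must be a clock_model")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(kind = model$kind, alpha = model$alpha, lambda = model$lambda,
               seed = model$seed, training_age_min = model$training_age_min,
               training_age_max = model$training_age_max,
               centenarian_weight = model$centenarian_weight,
               n_train = model$n_train,
               feature_means = as.list(model$feature_means),
               feature_sds = as.list(model$feature_sds))
  if (model$kind == "neural_net") {
    meta$y_mean <- model$fit$y_mean
    meta$y_sd <- model$fit$y_sd
    meta$hidden_sizes <- model$fit$hidden_sizes
    meta$feature_names <- model$fit$feature_names
    meta$layers <- setNames(
      purrr::map(model$fit$layers, function(l)
        list(dim = dim(l$W), W = as.numeric(l$W), b = as.numeric(l$b))),
      sprintf("layer%d", seq_along(model$fit$layers)))
  }
  jsonlite::write_json(meta, file.path(dir, "clock.json"), auto_unbox = TRUE,
                       digits = NA)
  if (model$kind == "elastic_net") {
    readr::write_csv(
      tibble::tibble(cpg_id = c("__intercept__", names(model$coefficients)),
                     weight = c(model$intercept, unname(model$coefficients))),
      file.path(dir, "coefficients.csv"))
  }
  invisible(dir)
}

#' Read a clock serialized by [write_clock()]
#' @param dir Directory holding `clock.json` (+ `coefficients.csv`).
#' @return A `clock_model` whose predictions match the original exactly.
#' @export
read_clock <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "clock.json"),
                              simplifyVector = TRUE)
  model <- list(kind = meta$kind, alpha = meta$alpha, lambda = meta$lambda,
                seed = meta$seed, training_age_min = meta$training_age_min,
                training_age_max = meta$training_age_max,
                centenarian_weight = meta$centenarian_weight,
                n_train = meta$n_train,
                feature_means = unlist(meta$feature_means),
                feature_sds = unlist(meta$feature_sds), cv = NULL, fit = NULL)
  if (meta$kind == "elastic_net") {
    coefs <- readr::read_csv(file.path(dir, "coefficients.csv"),
                             show_col_types = FALSE)
    model$intercept <- coefs$weight[coefs$cpg_id == "__intercept__"]
    keep <- coefs$cpg_id != "__intercept__"
    model$coefficients <- setNames(coefs$weight[keep], coefs$cpg_id[keep])
  } else {
    layers <- unname(purrr::map(meta$layers, function(l)
      list(W = matrix(as.numeric(l$W), l$dim[1], l$dim[2]),
           b = as.numeric(l$b))))
    model$intercept <- NA_real_
    model$fit <- structure(
      list(layers = layers, feature_names = meta$feature_names,
           feature_means = unlist(meta$feature_means),
           feature_sds = unlist(meta$feature_sds),
           y_mean = meta$y_mean, y_sd = meta$y_sd,
           hidden_sizes = meta$hidden_sizes),
      class = "mlp_fit")
  }
  structure(model, class = "clock_model")
}
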