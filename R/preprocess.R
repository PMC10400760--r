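#' Beta value from methylated/unmethylated intensities
#'
#' The standard Illumina-style methylation fraction
#' `max(M, 0) / (max(M, 0) + max(U, 0) + 100)`; the +100 offset stabilizes
#' low-intensity probes and keeps the result strictly below 1.
#'
#' @param M,U Methylated and unmethylated signal intensities (vectorized).
#' @return Beta values in `[0, 1)`.
#' @export
#' @examples
#' compute_beta(100, 100)  # 1/3
compute_beta <- function(M, U) {
  stop_if(any(!is.finite(M)) || any(!is.finite(U)), "intensities must be finite")
  m <- pmax(M, 0)
  u <- pmax(U, 0)
  m / (m + u + 100)
}

#' Pre-filter CpGs into positive, negative, and near-zero age-correlation sets
#'
#' Computes per-CpG Pearson correlation with age and selects the `n_pos` most
#' positively correlated, the `n_neg` most negatively correlated, and `n_null`
#' CpGs with the smallest `|r|` subject to `|r| <= eps_null`. Selection is
#' deterministic: ties are broken by CpG id, and the result does not depend on
#' the row order of the input.
#'
#' @param beta CpG x sample beta matrix.
#' @param ages Ages (years) aligned to the columns of `beta`.
#' @param n_pos,n_neg,n_null Set sizes.
#' @param eps_null Maximum `|r|` admitted to the null set.
#' @return A list of class `prefilter_result`: `pos_set`, `neg_set`,
#'   `null_set` (character vectors) and `r_by_cpg` (tibble `cpg_id`, `r`).
#' @export
prefilter_cpgs <- function(beta, ages, n_pos = 1000, n_neg = 1000,
                           n_null = 500, eps_null = 0.02) {
  check_beta_matrix(beta)
  stop_if(length(ages) != ncol(beta), "one age per sample required")
  stop_if(ncol(beta) < 3, "need at least 3 samples")
  stop_if(n_pos + n_neg + n_null > nrow(beta),
          "requested set sizes exceed the number of CpGs")
  r <- as.numeric(cor(t(beta), ages))
  r[is.na(r)] <- 0  # constant CpGs carry no age signal
  tab <- tibble::tibble(cpg_id = rownames(beta), r = r) %>%
    dplyr::arrange(.data$cpg_id)

  ord_pos <- order(-tab$r, tab$cpg_id)
  ord_neg <- order(tab$r, tab$cpg_id)
  pos_set <- tab$cpg_id[ord_pos][seq_len(n_pos)]
  neg_set <- tab$cpg_id[ord_neg][seq_len(n_neg)]
  taken <- c(pos_set, neg_set)
  null_pool <- tab %>%
    dplyr::filter(!.data$cpg_id %in% taken, abs(.data$r) <= eps_null) %>%
    dplyr::arrange(abs(.data$r), .data$cpg_id)
  null_set <- head(null_pool$cpg_id, n_null)
  if (length(null_set) < n_null)
    rlang::warn(sprintf("only %d CpGs satisfy |r| <= %g for the null set",
                        length(null_set), eps_null))
  structure(list(pos_set = pos_set, neg_set = neg_set, null_set = null_set,
                 r_by_cpg = tab),
            class = "prefilter_result")
}

#' @export
print.prefilter_result <- function(x, ...) {
  cat(sprintf("<prefilter_result> %d positive, %d negative, %d near-zero CpGs (of %d)\n",
              length(x$pos_set), length(x$neg_set), length(x$null_set),
              nrow(x$r_by_cpg)))
  invisible(x)
}

#' All selected CpG ids of a prefilter result
#' @param x A `prefilter_result`.
#' @return Character vector of selected CpG ids.
#' @export
selected_cpgs <- function(x) {
  stop_if(!inherits(x, "prefilter_result"), "`x` must be a prefilter_result")
  c(x$pos_set, x$neg_set, x$null_set)
}

#' Iterative residual-based outlier removal
#'
#' Repeatedly fits a preliminary clock on the current samples and drops every
#' sample whose absolute residual (predicted minus chronological age) exceeds
#' `abs_resid_years`, until no sample is removed or `max_iter` iterations.
#' This targets gross labeling/platemap errors, so the threshold is generous
#' by default.
#'
#' @param beta CpG x sample beta matrix.
#' @param sheet Sample sheet with `sample_id` and `age`.
#' @param clock_builder Function `(beta, sheet) -> clock_model` used for the
#'   preliminary fits; defaults to a lightly penalized elastic-net clock.
#' @param abs_resid_years Removal threshold in years.
#' @param max_iter Maximum number of fit/remove rounds.
#' @return A list: `kept_ids` and `report` (tibble
#'   `sample_id`, `iteration`, `residual_years`).
#' @export
remove_outliers <- function(beta, sheet, clock_builder = default_clock_builder(),
                            abs_resid_years = 30, max_iter = 3) {
  check_beta_matrix(beta)
  sheet <- align_sheet_to_beta(beta, check_sample_sheet(sheet))
  stop_if(abs_resid_years <= 0, "abs_resid_years must be > 0")
  kept <- colnames(beta)
  report <- list()
  for (it in seq_len(max_iter)) {
    sub_beta <- beta[, kept, drop = FALSE]
    sub_sheet <- sheet[match(kept, sheet$sample_id), , drop = FALSE]
    model <- clock_builder(sub_beta, sub_sheet)
    pred <- predict_age(model, sub_beta)
    resid <- pred$dnam_age - sub_sheet$age
    bad <- abs(resid) > abs_resid_years
    if (!any(bad)) break
    report[[it]] <- tibble::tibble(sample_id = kept[bad], iteration = it,
                                   residual_years = resid[bad])
    kept <- kept[!bad]
    stop_if(length(kept) == 0,
            "all samples flagged as outliers; check the threshold/clock")
  }
  report <- if (length(report)) dplyr::bind_rows(report) else
    tibble::tibble(sample_id = character(), iteration = integer(),
                   residual_years = numeric())
  list(kept_ids = kept, report = report)
}

#' Default preliminary clock used by [remove_outliers()]
#'
#' A weighted elastic-net clock with a short lambda path and cheap 5-fold
#' lambda selection — accurate enough to expose 40-year labeling errors.
#' @return A builder function `(beta, sheet) -> clock_model`.
#' @export
default_clock_builder <- function() {
  function(beta, sheet) {
    train_clock(beta, sheet, kind = "elastic_net", nlambda = 30,
                cv_folds = 5, seed = 20L)
  }
}

#' QC principal component analysis of samples
#'
#' PCA of the column-centered sample x CpG matrix via singular value
#' decomposition; used to check that the leading components capture known
#' structure (sex, batch) rather than artifacts.
#'
#' @param beta CpG x sample beta matrix.
#' @param n_components Number of PCs to return.
#' @return A list of class `pca_qc`: `variance_explained` (fractions, one per
#'   returned PC, non-increasing) and `scores` (tibble `sample_id`, `PC1`, ...).
#' @export
pca_qc <- function(beta, n_components = 5) {
  check_beta_matrix(beta)
  stop_if(nrow(beta) == 0 || ncol(beta) == 0, "empty beta matrix")
  stop_if(n_components > min(dim(beta)), "n_components exceeds matrix rank bound")
  X <- t(beta)  # samples x CpGs
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- tibble::as_tibble(pc$x[, seq_len(n_components), drop = FALSE])
  scores <- dplyr::bind_cols(tibble::tibble(sample_id = colnames(beta)), scores)
  structure(list(variance_explained = ve[seq_len(n_components)], scores = scores),
            class = "pca_qc")
}

#' @export
print.pca_qc <- function(x, ...) {
  cat("<pca_qc> variance explained:",
      paste0(sprintf("%.1f%%", 100 * x$variance_explained), collapse = ", "), "\n")
  invisible(x)
}

# per-CpG mean imputation of missing betas (flagged via message)
impute_beta <- function(beta) {
  if (!anyNA(beta)) return(beta)
  n_missing <- sum(is.na(beta))
  row_means <- rowMeans(beta, na.rm = TRUE)
  idx <- which(is.na(beta), arr.ind = TRUE)
  beta[idx] <- row_means[idx[, 1]]
  rlang::inform(sprintf("imputed %d missing beta values with per-CpG means", n_missing))
  beta
}
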