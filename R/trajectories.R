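# Nonlinear age-trajectory analysis: a LOWESS smoother (tricube-weighted
# local linear regression with bisquare robustness iterations) applied to
# individual CpGs and to mean methylation within chromatin states.

#' LOWESS smoother
#'
#' Locally weighted scatterplot smoothing: at each evaluation point a linear
#' fit over the `ceiling`-free `floor(frac * n)` nearest neighbours, weighted
#' by the tricube kernel of scaled distance, followed by `robust_iters`
#' bisquare reweighting passes on the residuals. Deterministic; no sampling.
#'
#' @param x,y Numeric data vectors (>= 5 points).
#' @param frac Span: fraction of points in each local window, in `(0, 1]`.
#' @param robust_iters Number of robustness iterations (default 3).
#' @param eval_x Points at which to evaluate the smooth (default: sorted
#'   distinct `x`).
#' @return A tibble `x`, `fitted`, ordered by `x`.
#' @export
lowess_smooth <- function(x, y, frac = 2/3, robust_iters = 3,
                          eval_x = sort(unique(x))) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  stop_if(n < 5, "need at least 5 points")
  stop_if(frac <= 0 || frac > 1, "frac must lie in (0, 1]")
  ns <- max(2L, min(n, floor(frac * n + 1e-7)))

  fit_at <- function(x0, rw) {
    d <- abs(x - x0)
    h <- sort(d, partial = ns)[ns]
    if (h <= 0) {
      w <- as.numeric(d == 0) * rw
      return(sum(w * y) / sum(w))
    }
    w <- (1 - pmin(d / h, 1)^3)^3 * rw
    sw <- sum(w)
    wx <- sum(w * x) / sw
    wy <- sum(w * y) / sw
    sxx <- sum(w * (x - wx)^2)
    if (sxx <= 1e-12 * h^2 * sw) return(wy)  # degenerate window: weighted mean
    b <- sum(w * (x - wx) * (y - wy)) / sxx
    wy + b * (x0 - wx)
  }

  rw <- rep(1, n)
  for (iter in seq_len(robust_iters + 1)) {
    if (iter > 1) {
      res <- y - vapply(x, fit_at, numeric(1), rw = rw)
      s <- median(abs(res))
      if (s == 0) break
      rw <- (1 - pmin(abs(res) / (6 * s), 1)^2)^2
      if (all(rw == 0)) rw <- rep(1, n)
    }
    if (iter == robust_iters + 1) break
  }
  tibble::tibble(x = eval_x,
                 fitted = vapply(eval_x, fit_at, numeric(1), rw = rw))
}

#' Per-sample mean methylation of a chromatin state or PRC layer
#'
#' Unweighted mean beta over the CpGs annotated to `target` (a chromatin
#' state label, or `"PRC1"` / `"PRC2"` for the polycomb layers), computed per
#' sample with missing betas excluded.
#'
#' @param beta CpG x sample beta matrix.
#' @param annotation Annotation tibble with `cpg_id`, `state` and (for PRC
#'   targets) the member columns.
#' @param target State label or `"PRC1"` / `"PRC2"`.
#' @return Named numeric vector, one mean per sample.
#' @export
state_mean_methylation <- function(beta, annotation, target) {
  ids <- if (target %in% c("PRC1", "PRC2")) {
    fl <- prc_flags(annotation)
    annotation$cpg_id[fl[[tolower(target)]] == 1]
  } else {
    annotation$cpg_id[annotation$state == target]
  }
  ids <- intersect(ids, rownames(beta))
  stop_if(length(ids) == 0, paste0("no CpGs for target ", target))
  colMeans(beta[ids, , drop = FALSE], na.rm = TRUE)
}

#' Age-trajectory reports for CpGs, states, and PRC layers
#'
#' For each target — a CpG id, a chromatin-state label, or `"PRC1"`/`"PRC2"`
#' — computes the Pearson correlation (and log10 p) of its methylation value
#' with age on the raw values, plus a LOWESS smooth evaluated at the distinct
#' observed ages.
#'
#' @param beta CpG x sample beta matrix.
#' @param sheet Sample sheet with `sample_id`, `age`.
#' @param targets Character vector of targets.
#' @param annotation Annotation tibble (needed for state/PRC targets).
#' @param frac LOWESS span.
#' @param robust_iters LOWESS robustness iterations.
#' @return A list of class `trajectory_report`: `report` (tibble `target`,
#'   `n`, `r`, `log10_p`) and `curves` (tibble `target`, `age`, `fitted`).
#' @export
trajectory_report <- function(beta, sheet, targets, annotation = NULL,
                              frac = 2/3, robust_iters = 3) {
  check_beta_matrix(beta)
  sheet <- align_sheet_to_beta(beta, check_sample_sheet(sheet))
  out <- purrr::map(targets, function(tg) {
    vals <- if (tg %in% rownames(beta)) {
      beta[tg, ]
    } else {
      stop_if(is.null(annotation),
              paste0("annotation required to resolve target ", tg))
      stop_if(!(tg %in% annotation$state || tg %in% c("PRC1", "PRC2")),
              paste0("unresolvable target: ", tg))
      state_mean_methylation(beta, annotation, tg)
    }
    ok <- is.finite(vals)
    r <- cor(vals[ok], sheet$age[ok])
    sm <- lowess_smooth(sheet$age[ok], vals[ok], frac = frac,
                        robust_iters = robust_iters)
    list(report = tibble::tibble(target = tg, n = sum(ok), r = r,
                                 log10_p = ewas_z(r, sum(ok))$log10_p),
         curve = tibble::tibble(target = tg, age = sm$x, fitted = sm$fitted))
  })
  structure(list(report = dplyr::bind_rows(purrr::map(out, "report")),
                 curves = dplyr::bind_rows(purrr::map(out, "curve"))),
            class = "trajectory_report")
}

#' @export
print.trajectory_report <- function(x, ...) {
  print(x$report)
  invisible(x)
}
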