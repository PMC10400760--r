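# Epigenetic age acceleration and its association machinery: OLS residuals,
# Cox proportional-hazards mortality models (Newton on the Breslow partial
# likelihood), inverse-variance fixed-effect meta-analysis, and the biweight
# midcorrelation screen.

#' Epigenetic age acceleration
#'
#' Residuals of an ordinary least-squares regression of DNAm age on
#' chronological age (with intercept). By construction the residuals have
#' mean zero and are uncorrelated with chronological age, removing its
#' confounding effect from downstream associations.
#'
#' @param dnam_age Predicted ages (years).
#' @param age Chronological ages (years), not constant.
#' @param sample_id Optional sample identifiers.
#' @return A tibble `sample_id`, `accel` (years; positive = epigenetically
#'   older than expected).
#' @export
compute_age_accel <- function(dnam_age, age, sample_id = NULL) {
  stop_if(length(dnam_age) != length(age), "equal-length vectors required")
  stop_if(length(age) < 3, "need at least 3 samples")
  stop_if(sd(age) == 0, "chronological age is constant; residuals undefined")
  fit <- lm.fit(cbind(1, age), dnam_age)
  tibble::tibble(
    sample_id = sample_id %||% as.character(seq_along(age)),
    accel = as.numeric(fit$residuals)
  )
}

#' Cox proportional-hazards fit (Breslow ties)
#'
#' Maximizes the Cox partial likelihood with the Breslow approximation for
#' tied event times by Newton iterations, stopping when the gradient norm
#' drops below `tol`. A monotone likelihood (perfect separation, diverging
#' coefficients) is flagged with a warning rather than returned silently.
#'
#' @param time Follow-up times (> 0).
#' @param event Event indicators (1 = death, 0 = censored); at least 1 event.
#' @param covariates Numeric matrix or data frame of covariates (finite).
#' @param tol Convergence tolerance on the gradient norm.
#' @param max_iter Newton iteration cap.
#' @return An object of class `cox_fit` with a per-covariate tibble
#'   (`term`, `log_hr`, `se`, `z`, `p`) plus `n`, `n_events`, `loglik`.
#' @export
fit_cox <- function(time, event, covariates, tol = 1e-8, max_iter = 30) {
  X <- as.matrix(covariates)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  stop_if(any(!is.finite(X)), "covariates must be finite")
  stop_if(length(time) != nrow(X) || length(event) != nrow(X),
          "time, event and covariates must align")
  stop_if(sum(event) < 1, "at least one event is required")
  n <- length(time); p <- ncol(X)

  ord <- order(time)
  tt <- time[ord]; ev <- event[ord]; Xo <- X[ord, , drop = FALSE]
  # first index sharing each time value -> risk set = indices first:n
  first_idx <- match(tt, tt)
  death_times <- unique(tt[ev == 1])

  beta <- rep(0, p)
  converged <- FALSE
  loglik <- NA_real_
  for (it in seq_len(max_iter)) {
    eta <- as.numeric(Xo %*% beta)
    eta <- eta - max(eta)  # guard overflow; Breslow terms are scale-invariant
    th <- exp(eta)
    rc0 <- rev(cumsum(rev(th)))                       # S0 at each position
    rc1 <- apply(Xo * th, 2, function(col) rev(cumsum(rev(col))))
    rc1 <- matrix(rc1, nrow = n)
    U <- rep(0, p); H <- matrix(0, p, p); ll <- 0
    for (dt in death_times) {
      at_risk <- first_idx[match(dt, tt)]
      d_idx <- which(tt == dt & ev == 1)
      d <- length(d_idx)
      s0 <- rc0[at_risk]
      s1 <- rc1[at_risk, ]
      rs <- at_risk:n
      s2 <- crossprod(Xo[rs, , drop = FALSE] * th[rs], Xo[rs, , drop = FALSE])
      xbar <- s1 / s0
      ll <- ll + sum(eta[d_idx]) - d * log(s0)
      U <- U + colSums(Xo[d_idx, , drop = FALSE]) - d * xbar
      H <- H + d * (s2 / s0 - tcrossprod(xbar))
    }
    loglik <- ll
    if (sqrt(sum(U^2)) < tol) { converged <- TRUE; break }
    step <- tryCatch(solve(H, U), error = function(e)
      rlang::abort("singular information matrix in Cox fit"))
    beta <- beta + step
    if (max(abs(beta)) > 30)
      rlang::warn("diverging Cox coefficients: likely monotone likelihood (perfect separation)")
  }
  if (!converged)
    rlang::warn("Cox Newton iterations did not reach the gradient tolerance")
  Hinv <- tryCatch(solve(H), error = function(e) {
    rlang::warn("singular information matrix (e.g. constant covariate): SEs undefined")
    matrix(NA_real_, p, p)
  })
  beta <- unname(beta)
  se <- unname(sqrt(diag(Hinv)))
  z <- beta / se
  structure(list(
    coefficients = tibble::tibble(term = colnames(X), log_hr = beta, se = se,
                                  z = z, p = 2 * pnorm(-abs(z))),
    n = n, n_events = sum(event), loglik = loglik, converged = converged),
    class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit> n = %d, events = %d, loglik = %.3f\n",
              x$n, x$n_events, x$loglik))
  print(x$coefficients)
  invisible(x)
}

#' @export
tidy.cox_fit <- function(x, ...) {
  dplyr::mutate(x$coefficients, hr = exp(.data$log_hr), .after = "log_hr")
}

#' @export
glance.cox_fit <- function(x, ...) {
  tibble::tibble(n = x$n, n_events = x$n_events, loglik = x$loglik,
                 converged = x$converged)
}

#' Inverse-variance weighted fixed-effect meta-analysis
#'
#' Combines per-stratum estimates with weights `w_i = 1/se_i^2`:
#' combined estimate `sum(w * theta) / sum(w)`, combined SE
#' `1/sqrt(sum(w))`, two-sided normal p value.
#'
#' @param estimates Per-stratum estimates.
#' @param ses Per-stratum standard errors (> 0).
#' @return A list of class `meta_estimate`: `estimate`, `se`, `z`, `p`,
#'   `strata` (input tibble).
#' @export
meta_fixed_effect <- function(estimates, ses) {
  stop_if(length(estimates) != length(ses), "estimates and ses must align")
  stop_if(length(estimates) < 1, "at least one stratum required")
  stop_if(any(ses <= 0), "all standard errors must be > 0")
  w <- 1 / ses^2
  est <- sum(w * estimates) / sum(w)
  se <- 1 / sqrt(sum(w))
  z <- est / se
  structure(list(estimate = est, se = se, z = z, p = 2 * pnorm(-abs(z)),
                 strata = tibble::tibble(estimate = estimates, se = ses)),
            class = "meta_estimate")
}

#' @export
print.meta_estimate <- function(x, ...) {
  cat(sprintf("<meta_estimate> %.4f (SE %.4f, z = %.2f, p = %.3g) from %d strata\n",
              x$estimate, x$se, x$z, x$p, nrow(x$strata)))
  invisible(x)
}

#' Biweight midcorrelation
#'
#' Tukey's robust correlation: deviations from the median are scaled by
#' `9 * MAD` (unscaled median absolute deviation), downweighted by the
#' bisquare weight `(1 - u^2)^2` inside `|u| < 1` and discarded outside, and
#' the weighted deviations are correlated. Falls back to the Pearson
#' correlation (with a warning) when either MAD is zero.
#'
#' @param x,y Numeric vectors of equal length (>= 3 complete pairs).
#' @return Correlation in `[-1, 1]`.
#' @export
bicor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  stop_if(length(x) < 3, "need at least 3 complete observations")
  wdev <- function(v) {
    med <- median(v)
    madv <- mad(v, constant = 1)
    if (madv == 0) return(NULL)
    u <- (v - med) / (9 * madv)
    w <- (1 - u^2)^2 * (abs(u) < 1)
    (v - med) * w
  }
  dx <- wdev(x); dy <- wdev(y)
  if (is.null(dx) || is.null(dy)) {
    rlang::warn("zero MAD: falling back to Pearson correlation")
    return(cor(x, y))
  }
  stop_if(sum(dx^2) == 0 || sum(dy^2) == 0,
          "all observations downweighted to zero")
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

#' Stratified biweight-midcorrelation meta-analysis
#'
#' For each variable: the biweight midcorrelation with age acceleration is
#' computed within each stratum (strata with fewer than 4 complete
#' observations are skipped with a message), Fisher-z transformed with
#' SE `1/sqrt(n - 3)`, combined by inverse-variance fixed-effect
#' meta-analysis, and back-transformed to the correlation scale.
#'
#' @param data A data frame holding acceleration, variables and strata.
#' @param accel Name of the age-acceleration column.
#' @param variables Character vector of variable column names to screen.
#' @param strata Name of the stratum label column.
#' @return A tibble `variable`, `stratum_count`, `meta_bicor`, `z`, `p`.
#' @export
stratified_bicor_meta <- function(data, accel = "accel", variables,
                                  strata = "cohort") {
  stop_if(!accel %in% names(data), paste0("missing column: ", accel))
  stop_if(!strata %in% names(data), paste0("missing column: ", strata))
  stop_if(!all(variables %in% names(data)), "missing variable column(s)")
  labs <- unique(data[[strata]])
  purrr::map(variables, function(v) {
    ests <- list()
    for (lab in labs) {
      sub <- data[data[[strata]] == lab, c(accel, v)]
      sub <- sub[stats::complete.cases(sub), ]
      if (nrow(sub) < 4) {
        rlang::inform(sprintf("stratum '%s' skipped for %s (n = %d < 4)",
                              lab, v, nrow(sub)))
        next
      }
      rho <- bicor(sub[[accel]], sub[[v]])
      rho <- max(min(rho, 1 - 1e-12), -1 + 1e-12)
      ests[[length(ests) + 1]] <- c(z = atanh(rho), se = 1 / sqrt(nrow(sub) - 3))
    }
    stop_if(length(ests) == 0, paste0("no usable strata for ", v))
    em <- do.call(rbind, ests)
    meta <- meta_fixed_effect(em[, "z"], em[, "se"])
    tibble::tibble(variable = v, stratum_count = nrow(em),
                   meta_bicor = tanh(meta$estimate), z = meta$z, p = meta$p)
  }) %>% dplyr::bind_rows()
}

#' Stratified Cox mortality association of age acceleration
#'
#' Fits, within each stratum, a Cox model of time-to-death on age
#' acceleration adjusted for the requested covariates (sex is coded
#' female = 0 / male = 1 when present), then combines the per-stratum
#' acceleration log hazard ratios by inverse-variance fixed-effect
#' meta-analysis.
#'
#' @param data Data frame with `time`, `event`, the acceleration column, and
#'   covariates.
#' @param accel Name of the age-acceleration column.
#' @param covariates Adjustment covariate column names (default age + sex).
#' @param strata Name of the stratum label column.
#' @param min_events Strata with fewer events are skipped with a message.
#' @return A tibble `stratum`, `log_hr`, `se`, `hr`, `p`, `n`, `n_events`
#'   with one extra `meta` row for the combined estimate.
#' @export
mortality_meta <- function(data, accel = "accel",
                           covariates = c("age", "sex"), strata = "cohort",
                           min_events = 5) {
  needed <- c("time", "event", accel, covariates, strata)
  stop_if(!all(needed %in% names(data)), "missing required column(s)")
  rows <- list()
  for (lab in unique(data[[strata]])) {
    sub <- data[data[[strata]] == lab, , drop = FALSE]
    if (sum(sub$event) < min_events) {
      rlang::inform(sprintf("stratum '%s' skipped (%d events < %d)",
                            lab, sum(sub$event), min_events))
      next
    }
    Xc <- sub[, c(accel, covariates), drop = FALSE]
    if ("sex" %in% names(Xc)) Xc$sex <- as.numeric(Xc$sex == "M")
    Xc <- as.matrix(Xc)
    # an adjustment covariate constant within a stratum carries no information
    keep_col <- c(TRUE, apply(Xc[, -1, drop = FALSE], 2, var) > 0)
    fit <- fit_cox(sub$time, sub$event, Xc[, keep_col, drop = FALSE])
    a <- fit$coefficients[1, ]
    rows[[length(rows) + 1]] <- tibble::tibble(
      stratum = lab, log_hr = a$log_hr, se = a$se, hr = exp(a$log_hr),
      p = a$p, n = fit$n, n_events = fit$n_events)
  }
  stop_if(length(rows) == 0, "no stratum had enough events")
  tab <- dplyr::bind_rows(rows)
  meta <- meta_fixed_effect(tab$log_hr, tab$se)
  dplyr::bind_rows(tab, tibble::tibble(
    stratum = "meta", log_hr = meta$estimate, se = meta$se,
    hr = exp(meta$estimate), p = meta$p, n = sum(tab$n),
    n_events = sum(tab$n_events)))
}
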