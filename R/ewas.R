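# Age-stratified epigenome-wide correlation screening: per-CpG Pearson r with
# age, t-based two-sided p (carried on the log10 scale so values far below
# double precision survive), probit Z scores, top-K selection, and
# cross-age-group concordance.

#' Correlate every CpG with chronological age
#'
#' Per CpG: Pearson correlation with age over samples with observed beta,
#' two-sided p from `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of
#' freedom, and a signed probit Z score `z = sign(r) * qnorm(1 - p/2)`.
#' The p value is computed and stored on the log10 scale (floored at -320),
#' so extreme associations never underflow. CpGs with fewer than 4 usable
#' samples or zero variance are reported with `NA` statistics rather than
#' dropped.
#'
#' @param beta CpG x sample beta matrix.
#' @param ages Ages (years) aligned to columns.
#' @param group_label Optional label attached to the result.
#' @return A tibble of class `ewas_result`: `cpg_id`, `group`, `n`, `r`, `z`,
#'   `log10_p`.
#' @export
correlate_cpgs_age <- function(beta, ages, group_label = "all") {
  check_beta_matrix(beta)
  stop_if(length(ages) != ncol(beta), "one age per sample required")
  n_obs <- rowSums(is.finite(beta))
  r <- suppressWarnings(as.numeric(cor(t(beta), ages,
                                       use = "pairwise.complete.obs")))
  row_sd <- apply(beta, 1, sd, na.rm = TRUE)
  bad <- n_obs < 4 | row_sd == 0 | sd(ages) == 0 | is.na(r)
  r[bad] <- NA_real_
  stats <- ewas_z(r, unname(n_obs))
  out <- tibble::tibble(cpg_id = rownames(beta), group = group_label,
                        n = unname(n_obs), r = unname(r),
                        z = unname(stats$z), log10_p = unname(stats$log10_p))
  class(out) <- c("ewas_result", class(out))
  out
}

# signed probit z and log10 two-sided p from Pearson r at sample size n
# (vectorized; r may contain NA)
ewas_z <- function(r, n) {
  r2 <- pmin(r^2, 1 - 1e-15)
  tstat <- abs(r) * sqrt((n - 2) / (1 - r2))
  log_p_half <- pt(tstat, df = n - 2, lower.tail = FALSE, log.p = TRUE)
  log10_p <- pmax((log_p_half + log(2)) / log(10), -320)
  z <- sign(r) * qnorm(log_p_half, lower.tail = FALSE, log.p = TRUE)
  list(z = z, log10_p = log10_p)
}

#' Default age-group definitions for the stratified EWAS
#'
#' Young `[0, 40)`, middle `[40, 90)`, old `[90, 115]`: bounds are
#' lower-inclusive, upper-exclusive except the final bound.
#' @return A tibble `group`, `min_age`, `max_age`.
#' @export
ewas_age_groups <- function() {
  tibble::tibble(group = c("young", "middle", "old"),
                 min_age = c(0, 40, 90), max_age = c(40, 90, 115))
}

#' Age-stratified EWAS
#'
#' Subsets samples into the given age groups (lower bound inclusive, upper
#' exclusive except for the last group, which includes its upper bound) and
#' runs [correlate_cpgs_age()] within each.
#'
#' @param beta CpG x sample beta matrix.
#' @param sheet Sample sheet with `sample_id` and `age`.
#' @param groups Group definition tibble as from [ewas_age_groups()].
#' @return A tibble of class `ewas_result` with one block per non-empty group;
#'   empty groups raise a warning and contribute no rows.
#' @export
stratify_ewas <- function(beta, sheet, groups = ewas_age_groups()) {
  check_beta_matrix(beta)
  sheet <- align_sheet_to_beta(beta, check_sample_sheet(sheet))
  stop_if(any(groups$min_age >= groups$max_age), "degenerate group bounds")
  last <- which.max(groups$max_age)
  out <- purrr::map(seq_len(nrow(groups)), function(g) {
    inc_upper <- g == last
    sel <- sheet$age >= groups$min_age[g] &
      (sheet$age < groups$max_age[g] |
         (inc_upper & sheet$age == groups$max_age[g]))
    if (!any(sel)) {
      rlang::warn(sprintf("age group '%s' is empty", groups$group[g]))
      return(NULL)
    }
    correlate_cpgs_age(beta[, sel, drop = FALSE], sheet$age[sel],
                       group_label = groups$group[g])
  }) %>% dplyr::bind_rows()
  class(out) <- c("ewas_result", class(out))
  out
}

#' Top-K age-related CpGs by Z score
#'
#' Positive direction: the `k` largest Z scores among CpGs with `z > 0`;
#' negative: the `k` smallest among `z < 0`. Ties break by CpG id. If fewer
#' than `k` CpGs carry the requested sign, all of them are returned with a
#' warning.
#'
#' @param ewas An `ewas_result` (a single group).
#' @param k Number of CpGs.
#' @param direction `"positive"` or `"negative"`.
#' @return Character vector of CpG ids.
#' @export
top_k_cpgs <- function(ewas, k, direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  stop_if(dplyr::n_distinct(ewas$group) > 1,
          "pass a single EWAS group to top_k_cpgs()")
  tab <- dplyr::filter(ewas, !is.na(.data$z))
  tab <- if (direction == "positive") {
    dplyr::arrange(dplyr::filter(tab, .data$z > 0), dplyr::desc(.data$z),
                   .data$cpg_id)
  } else {
    dplyr::arrange(dplyr::filter(tab, .data$z < 0), .data$z, .data$cpg_id)
  }
  if (nrow(tab) < k)
    rlang::warn(sprintf("only %d CpGs with %s z; returning all of them",
                        nrow(tab), direction))
  head(tab$cpg_id, k)
}

#' Concordance of age effects between two EWAS groups
#'
#' Pearson correlation of the per-CpG Z-score vectors over the CpGs with
#' defined Z in both groups.
#'
#' @param ewas_a,ewas_b Two `ewas_result` objects (one group each).
#' @return A list: `r`, `log10_p`, `n_cpgs`.
#' @export
crossgroup_concordance <- function(ewas_a, ewas_b) {
  m <- dplyr::inner_join(
    dplyr::select(dplyr::filter(ewas_a, !is.na(.data$z)), "cpg_id", za = "z"),
    dplyr::select(dplyr::filter(ewas_b, !is.na(.data$z)), "cpg_id", zb = "z"),
    by = "cpg_id")
  stop_if(nrow(m) < 3, "fewer than 3 CpGs shared between the two results")
  r <- cor(m$za, m$zb)
  list(r = r, log10_p = ewas_z(r, nrow(m))$log10_p, n_cpgs = nrow(m))
}

#' Manhattan-plot export table
#'
#' Joins EWAS statistics to CpG coordinates and flags genome-wide significant
#' hits at `p < 1e-7` (strict inequality). CpGs missing from the annotation
#' are dropped with a message reporting the count.
#'
#' @param ewas An `ewas_result` (single group).
#' @param annotation Annotation tibble with `cpg_id`, `chrom`, `start`
#'   (0-based), `gene`.
#' @return A tibble `chrom`, `pos`, `cpg_id`, `gene`, `r`, `z`, `p`,
#'   `minus_log10_p`, `genomewide_flag`.
#' @export
export_manhattan <- function(ewas, annotation) {
  m <- dplyr::inner_join(ewas, annotation, by = "cpg_id")
  dropped <- nrow(ewas) - nrow(m)
  if (dropped > 0)
    rlang::inform(sprintf("%d CpGs without annotation dropped", dropped))
  m %>%
    dplyr::mutate(pos = .data$start,
                  p = 10^.data$log10_p,
                  minus_log10_p = -.data$log10_p,
                  genomewide_flag = .data$log10_p < -7) %>%
    dplyr::select("chrom", "pos", "cpg_id", "gene", "r", "z", "p",
                  "minus_log10_p", "genomewide_flag")
}
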