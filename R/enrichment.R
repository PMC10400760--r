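# Chromatin-state and polycomb enrichment of CpG sets: one-sided
# hypergeometric tails computed in log space, 2x2 odds ratios with Haldane
# correction, and the signed -log10(p) summary matrix.

#' One-sided hypergeometric tail probability
#'
#' For `X ~ Hypergeometric(N, K, n)` (population `N`, `K` marked, draw `n`):
#' upper tail `P(X >= k)`, lower tail `P(X <= k)`. Probabilities are
#' accumulated in log space from `lchoose` terms, so extreme tails do not
#' underflow.
#'
#' @param k Observed overlap count.
#' @param K Marked population size.
#' @param n Draw (query) size.
#' @param N Population size.
#' @param side `"upper"` (enrichment) or `"lower"` (depletion).
#' @param log10p Return the log10 probability instead.
#' @return The tail probability (or its log10).
#' @export
#' @examples
#' hypergeom_tail(5, K = 8, n = 6, N = 20, side = "upper")  # ~0.01806
hypergeom_tail <- function(k, K, n, N, side = c("upper", "lower"),
                           log10p = FALSE) {
  side <- match.arg(side)
  stop_if(K > N || n > N, "K and n must not exceed N")
  stop_if(k < 0 || k > min(K, n), "k must lie in [0, min(K, n)]")
  lo <- max(0, n - (N - K))
  hi <- min(K, n)
  j <- if (side == "upper") k:hi else lo:min(k, hi)
  lp <- lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)
  out <- log_sum_exp(lp)
  out <- min(out, 0)  # guard tiny positive rounding
  if (log10p) out / log(10) else exp(out)
}

#' Sample odds ratio of a 2x2 overlap table
#'
#' The table is `(k, n - k; K - k, N - K - n + k)`; with any zero cell the
#' Haldane-Anscombe correction (+0.5 to all cells) is applied and flagged via
#' the `"corrected"` attribute.
#'
#' @inheritParams hypergeom_tail
#' @return The odds ratio (attribute `corrected` is `TRUE` when the +0.5
#'   correction was used).
#' @export
odds_ratio <- function(k, K, n, N) {
  a <- k; b <- n - k; c <- K - k; d <- N - K - n + k
  stop_if(any(c(a, b, c, d) < 0), "negative cell in the 2x2 table")
  corrected <- any(c(a, b, c, d) == 0)
  if (corrected) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
  structure((a * d) / (b * c), corrected = corrected)
}

#' Membership indicators for polycomb repressive complexes
#'
#' A CpG counts as PRC1-bound when at least two of RING1, RNF2, BMI1 bind,
#' and PRC2-bound when at least two of EED, SUZ12, EZH2 bind.
#'
#' @param annotation Tibble with binary member columns `RING1`, `RNF2`,
#'   `BMI1`, `EED`, `SUZ12`, `EZH2`.
#' @return A tibble `cpg_id` (if present), `prc1`, `prc2` (0/1).
#' @export
prc_flags <- function(annotation) {
  prc1_members <- c("RING1", "RNF2", "BMI1")
  prc2_members <- c("EED", "SUZ12", "EZH2")
  missing <- setdiff(c(prc1_members, prc2_members), names(annotation))
  stop_if(length(missing) > 0,
          paste0("missing PRC member column(s): ", paste(missing, collapse = ", ")))
  out <- tibble::tibble(
    prc1 = as.integer(rowSums(annotation[, prc1_members]) >= 2),
    prc2 = as.integer(rowSums(annotation[, prc2_members]) >= 2))
  if ("cpg_id" %in% names(annotation))
    out <- dplyr::bind_cols(annotation["cpg_id"], out)
  out
}

#' Chromatin-state (and PRC) enrichment of a CpG set
#'
#' One-sided hypergeometric enrichment and depletion tests of a query CpG set
#' against each chromatin state present in the background, plus — when PRC
#' member columns are available — the non-exclusive PRC1/PRC2 annotation
#' layers. The enrichment p includes the observed count (`P(X >= k)`), the
#' depletion p is `P(X <= k)`, and the signed score is
#' `-log10(min p) * sign(OR - 1)` (0 when `OR = 1`).
#'
#' @param query Character vector of CpG ids (must be a subset of
#'   `background`).
#' @param annotation Annotation tibble with `cpg_id`, `state`, and optionally
#'   the PRC member columns.
#' @param background Character vector of background CpG ids; every one must
#'   be annotated. Default: all annotated CpGs.
#' @param set_label Label for the query set.
#' @return A tibble of class `enrichment_result`: `set_label`, `state`, `k`,
#'   `n_set`, `K_state`, `N`, `odds_ratio`, `or_corrected`,
#'   `log10_p_enrich`, `log10_p_deplete`, `signed_score`.
#' @export
enrich_states <- function(query, annotation, background = annotation$cpg_id,
                          set_label = "query") {
  stop_if(!all(c("cpg_id", "state") %in% names(annotation)),
          "annotation needs `cpg_id` and `state` columns")
  stop_if(anyDuplicated(annotation$cpg_id) > 0, "duplicate CpGs in annotation")
  stop_if(!all(background %in% annotation$cpg_id),
          "every background CpG must be annotated")
  stop_if(!all(query %in% background), "query must be a subset of the background")
  ann <- annotation[match(background, annotation$cpg_id), , drop = FALSE]
  in_query <- ann$cpg_id %in% query
  N <- length(background)
  n_set <- length(query)

  layers <- lapply(split(ann$cpg_id, ann$state), identity)
  if (all(c("RING1", "RNF2", "BMI1", "EED", "SUZ12", "EZH2") %in% names(ann))) {
    fl <- prc_flags(ann)
    layers$PRC1 <- ann$cpg_id[fl$prc1 == 1]
    layers$PRC2 <- ann$cpg_id[fl$prc2 == 1]
  }
  out <- purrr::imap(layers, function(members, lab) {
    K <- length(members)
    k <- sum(query %in% members)
    or <- odds_ratio(k, K, n_set, N)
    lpe <- hypergeom_tail(k, K, n_set, N, "upper", log10p = TRUE)
    lpd <- hypergeom_tail(k, K, n_set, N, "lower", log10p = TRUE)
    s <- sign(as.numeric(or) - 1)
    tibble::tibble(set_label = set_label, state = lab, k = k, n_set = n_set,
                   K_state = K, N = N, odds_ratio = as.numeric(or),
                   or_corrected = attr(or, "corrected"),
                   log10_p_enrich = lpe, log10_p_deplete = lpd,
                   signed_score = if (s == 0) 0 else -min(lpe, lpd) * s)
  }) %>% dplyr::bind_rows()
  class(out) <- c("enrichment_result", class(out))
  out
}

#' Signed -log10(p) state-by-set matrix
#'
#' Pivots enrichment results for several CpG sets into a states x sets table
#' of signed scores, optionally keeping only states whose minimum p (either
#' tail) beats a display threshold in at least one set.
#'
#' @param results An `enrichment_result` covering one or more `set_label`s
#'   over a consistent state universe.
#' @param p_threshold Optional display filter (e.g. `1e-10`).
#' @return A tibble with `state` and one signed-score column per set.
#' @export
signed_log10p_matrix <- function(results, p_threshold = NULL) {
  wide <- results %>%
    dplyr::select("state", "set_label", "signed_score") %>%
    tidyr::pivot_wider(names_from = "set_label", values_from = "signed_score")
  if (!is.null(p_threshold)) {
    keep <- results %>%
      dplyr::group_by(.data$state) %>%
      dplyr::summarise(minp = min(pmin(.data$log10_p_enrich,
                                       .data$log10_p_deplete))) %>%
      dplyr::filter(.data$minp < log10(p_threshold)) %>%
      dplyr::pull("state")
    wide <- dplyr::filter(wide, .data$state %in% keep)
  }
  wide
}
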