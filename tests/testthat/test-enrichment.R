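# exhaustive hypergeometric tail by direct enumeration of the pmf
enum_tail <- function(k, K, n, N, side) {
  lo <- max(0, n - (N - K)); hi <- min(K, n)
  pmf <- choose(K, lo:hi) * choose(N - K, n - (lo:hi)) / choose(N, n)
  j <- lo:hi
  if (side == "upper") sum(pmf[j >= k]) else sum(pmf[j <= k])
}

test_that("hypergeometric tails match exhaustive enumeration (worked example)", {
  expect_equal(hypergeom_tail(0, 8, 6, 20, "upper"), 1)
  expect_equal(hypergeom_tail(5, 8, 6, 20, "upper"), 700 / 38760,
               tolerance = 1e-12)
  # tail identity: upper + lower - P(X = k) = 1
  for (k in 0:6) {
    up <- hypergeom_tail(k, 8, 6, 20, "upper")
    lo <- hypergeom_tail(k, 8, 6, 20, "lower")
    pk <- choose(8, k) * choose(12, 6 - k) / choose(20, 6)
    expect_equal(up + lo - pk, 1, tolerance = 1e-12)
  }
  expect_error(hypergeom_tail(7, 8, 6, 20), "k must lie")
  expect_error(hypergeom_tail(2, 25, 6, 20), "exceed")
})

test_that("hypergeometric tails agree with enumeration over a small-N sweep", {
  # systematic sweep over small populations (full N <= 30 sweep runs in the
  # acceptance suite)
  for (N in c(5, 9, 14, 20)) {
    for (K in 0:N) {
      for (n in c(0, 1, N %/% 2, N)) {
        for (k in unique(c(max(0, n - (N - K)), min(K, n)))) {
          expect_equal(hypergeom_tail(k, K, n, N, "upper"),
                       enum_tail(k, K, n, N, "upper"), tolerance = 1e-12)
          expect_equal(hypergeom_tail(k, K, n, N, "lower"),
                       enum_tail(k, K, n, N, "lower"), tolerance = 1e-12)
        }
      }
    }
  }
  # log-space path agrees with R's phyper far in the tail
  expect_equal(hypergeom_tail(150, 200, 300, 2000, "upper", log10p = TRUE),
               phyper(149, 200, 1800, 300, lower.tail = FALSE, log.p = TRUE) /
                 log(10), tolerance = 1e-9)
})

test_that("odds ratios follow the 2x2 arithmetic with Haldane correction", {
  expect_equal(as.numeric(odds_ratio(2, 4, 5, 10)), 1)  # proportional table
  expect_equal(as.numeric(odds_ratio(5, 8, 6, 20)), (5 * 11) / (1 * 3),
               tolerance = 1e-12)
  # k = n gives a zero cell -> corrected, finite, > 1
  or <- odds_ratio(6, 8, 6, 20)
  expect_true(attr(or, "corrected"))
  expect_true(is.finite(as.numeric(or)) && as.numeric(or) > 1)
  expect_error(odds_ratio(5, 4, 5, 10), "negative cell")
})

test_that("PRC flags require binding of at least two members", {
  ann <- tibble::tibble(cpg_id = paste0("cg", 1:4),
                        RING1 = c(1, 1, 0, 1), RNF2 = c(1, 0, 0, 1),
                        BMI1 = c(0, 0, 0, 1),
                        EED = c(1, 1, 1, 1), SUZ12 = c(0, 1, 0, 1),
                        EZH2 = c(0, 0, 0, 1))
  fl <- prc_flags(ann)
  expect_equal(fl$prc1, c(1L, 0L, 0L, 1L))
  expect_equal(fl$prc2, c(0L, 1L, 0L, 1L))
  expect_error(prc_flags(ann[, -2]), "RING1")
})

test_that("state enrichment handles boundaries and matches enumeration", {
  ann <- tibble::tibble(
    cpg_id = sprintf("cg%03d", 1:100),
    state = rep(c("BivProm2", "Quies1", "EnhA1", "TxEx4", "TSS1"),
                times = c(20, 30, 20, 15, 15)))
  # query entirely inside one state of size 20 against background 100
  query <- ann$cpg_id[ann$state == "BivProm2"][1:10]
  res <- enrich_states(query, ann)
  row <- res[res$state == "BivProm2", ]
  expect_equal(row$k, 10L)
  expect_equal(10^row$log10_p_enrich, enum_tail(10, 20, 10, 100, "upper"),
               tolerance = 1e-10)
  expect_gt(row$odds_ratio, 1)
  # partition property: state sizes sum to the background size
  expect_equal(sum(res$K_state[res$state %in% unique(ann$state)]), 100L)
  # query = background: every state has k = K and enrichment p = 1
  res_all <- enrich_states(ann$cpg_id, ann)
  expect_equal(res_all$k, res_all$K_state)
  expect_equal(10^res_all$log10_p_enrich, rep(1, nrow(res_all)))
  expect_error(enrich_states(c(query, "cg999"), ann), "subset")
  # relabeling CpG ids leaves the p values unchanged
  ann2 <- ann
  ann2$cpg_id <- sprintf("probe%03d", 100:1)
  query2 <- ann2$cpg_id[ann2$state == "BivProm2"][1:10]
  res2 <- enrich_states(query2, ann2)
  expect_equal(res2$log10_p_enrich[match(res$state, res2$state)],
               res$log10_p_enrich, tolerance = 1e-12)
})

test_that("planted bivalent enrichment is recovered and ranks first", {
  hits <- vapply(1:20, function(s) {
    co <- simulate_cohort(sim_config(n_samples = 150, n_cpgs = 600, seed = s))
    ew <- correlate_cpgs_age(co$beta, co$samples$age)
    top <- top_k_cpgs(ew, 60, "positive")
    res <- enrich_states(top, co$annotation)
    states_only <- res[!res$state %in% c("PRC1", "PRC2"), ]
    best <- states_only$state[which.max(states_only$signed_score)]
    best %in% c("BivProm1", "BivProm2", "ReprPC1")
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  # and the planted target is individually significant on the default cohort
  co <- default_cohort()
  ew <- correlate_cpgs_age(co$beta, co$samples$age)
  top <- top_k_cpgs(ew, 200, "positive")
  res <- enrich_states(top, co$annotation)
  target <- res[res$state %in% c("BivProm1", "BivProm2", "ReprPC1"), ]
  expect_true(any(target$odds_ratio > 1 & target$log10_p_enrich < -2))
})

test_that("the signed score matrix pivots and filters by minimum p", {
  res <- dplyr::bind_rows(
    tibble::tibble(set_label = "pos", state = c("A", "B"), k = c(5L, 1L),
                   n_set = 10L, K_state = c(10L, 50L), N = 100L,
                   odds_ratio = c(9, 0.1), or_corrected = FALSE,
                   log10_p_enrich = c(-12, -0.01), log10_p_deplete = c(-0.001, -3),
                   signed_score = c(12, -3)),
    tibble::tibble(set_label = "neg", state = c("A", "B"), k = c(1L, 4L),
                   n_set = 10L, K_state = c(10L, 50L), N = 100L,
                   odds_ratio = c(1, 2), or_corrected = FALSE,
                   log10_p_enrich = c(-0.4, -4), log10_p_deplete = c(-0.6, -0.1),
                   signed_score = c(0, 4)))
  wide <- signed_log10p_matrix(res)
  expect_equal(names(wide), c("state", "pos", "neg"))
  expect_equal(wide$pos, c(12, -3))
  expect_equal(wide$neg, c(0, 4))
  filt <- signed_log10p_matrix(res, p_threshold = 1e-10)
  expect_equal(filt$state, "A")  # only A has any p below 1e-10
})
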