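test_that("per-CpG age correlation matches textbook formulas", {
  ages <- c(42, 50, 59, 67, 80, 95)
  beta <- toy_beta(ages)
  ew <- correlate_cpgs_age(beta, ages)
  expect_equal(ew$r[ew$cpg_id == "cgA"], 1, tolerance = 1e-12)
  # |r| = 1 at n = 6: the t statistic explodes, p collapses far beyond
  # anything a 4-df tail can reach for real data
  expect_lte(ew$log10_p[ew$cpg_id == "cgA"], -25)
  expect_equal(ew$r[ew$cpg_id == "cgB"], -1, tolerance = 1e-12)

  # hand fixture: r, t, p via brute-force arithmetic
  b <- c(0.21, 0.25, 0.22, 0.31, 0.29, 0.38)
  m <- rbind(cgX = b)
  colnames(m) <- paste0("S", 1:6)
  ew2 <- correlate_cpgs_age(m, ages)
  r_hand <- sum((b - mean(b)) * (ages - mean(ages))) /
    sqrt(sum((b - mean(b))^2) * sum((ages - mean(ages))^2))
  t_hand <- r_hand * sqrt(4 / (1 - r_hand^2))
  p_hand <- 2 * pt(abs(t_hand), df = 4, lower.tail = FALSE)
  expect_equal(ew2$r, r_hand, tolerance = 1e-12)
  expect_equal(10^ew2$log10_p, p_hand, tolerance = 1e-10)
  expect_equal(ew2$z, sign(r_hand) * qnorm(1 - p_hand / 2), tolerance = 1e-8)
})

test_that("z is a sign-consistent monotone transform of the p value", {
  ages <- seq(40, 100, length.out = 30)
  set.seed(31)
  beta <- matrix(runif(20 * 30), 20, 30,
                 dimnames = list(paste0("cg", 1:20), paste0("S", 1:30)))
  beta[1, ] <- clamp01(ages / 150 + rnorm(30, 0, 0.02))
  ew <- correlate_cpgs_age(beta, ages)
  expect_true(all(sign(ew$z) == sign(ew$r), na.rm = TRUE))
  pos <- dplyr::filter(ew, .data$z > 0)
  expect_equal(order(pos$z), order(-pos$log10_p))
  # permutation of samples leaves every statistic unchanged
  perm <- sample(30)
  ew_p <- correlate_cpgs_age(beta[, perm], ages[perm])
  expect_equal(ew$r, ew_p$r, tolerance = 1e-12)
  expect_equal(ew$z, ew_p$z, tolerance = 1e-12)
})

test_that("age-group stratification uses lower-inclusive bounds", {
  ages <- c(39.9, 40, 50, 89.9, 90, 115)
  beta <- matrix(runif(5 * 6, 0.3, 0.7), 5, 6,
                 dimnames = list(paste0("cg", 1:5), paste0("S", 1:6)))
  sheet <- tibble::tibble(sample_id = paste0("S", 1:6), age = ages)
  ew <- stratify_ewas(beta, sheet)
  # young gets only 39.9; middle gets 40, 50, 89.9; old gets 90 and 115
  expect_equal(ew$n[ew$group == "young"][1], 1L)
  expect_equal(ew$n[ew$group == "middle"][1], 3L)
  expect_equal(ew$n[ew$group == "old"][1], 2L)

  # all samples in one group -> the other groups are warned empty
  sheet50 <- tibble::tibble(sample_id = paste0("S", 1:6), age = rep(50, 6))
  w <- testthat::capture_warnings(ew50 <- stratify_ewas(beta, sheet50))
  expect_true(all(grepl("empty", w)) && length(w) == 2)
  expect_equal(unique(ew50$group), "middle")
})

test_that("planted CpGs correlate positively in every age group", {
  co <- default_cohort()
  pos_ids <- co$cpg_spec$cpg_id[co$cpg_spec$class_label == "pos_linear"][1:20]
  ew <- stratify_ewas(co$beta[pos_ids, ], co$samples,
                      groups = ewas_age_groups()[2:3, ])
  frac_pos <- mean(ew$r > 0, na.rm = TRUE)
  expect_gte(frac_pos, 0.9)
})

test_that("top-K selection matches a brute-force sort with id tie-breaks", {
  ages <- seq(40, 100, length.out = 40)
  set.seed(32)
  beta <- matrix(clamp01(outer(seq(-0.004, 0.005, length.out = 10), ages - 70) +
                           0.5 + rnorm(400, 0, 0.02)),
                 10, 40, dimnames = list(paste0("cg", 1:10), paste0("S", 1:40)))
  ew <- correlate_cpgs_age(beta, ages)
  top_pos <- top_k_cpgs(ew, 3, "positive")
  ord <- ew$cpg_id[order(-ew$z, ew$cpg_id)]
  expect_equal(top_pos, ord[1:3])
  expect_true(all(ew$z[match(top_pos, ew$cpg_id)] > 0))
  top1_neg <- top_k_cpgs(ew, 1, "negative")
  expect_equal(top1_neg, ew$cpg_id[which.min(ew$z)])
  # requesting more than available returns all of that sign with a warning
  n_pos <- sum(ew$z > 0)
  expect_warning(allpos <- top_k_cpgs(ew, 10, "positive"), "only")
  expect_length(allpos, n_pos)
})

test_that("cross-group concordance behaves at its algebraic extremes", {
  ages <- seq(40, 100, length.out = 30)
  set.seed(33)
  beta <- matrix(runif(15 * 30), 15, 30,
                 dimnames = list(paste0("cg", 1:15), paste0("S", 1:30)))
  ew <- correlate_cpgs_age(beta, ages)
  expect_equal(crossgroup_concordance(ew, ew)$r, 1, tolerance = 1e-12)
  flipped <- ew
  flipped$z <- -flipped$z
  expect_equal(crossgroup_concordance(ew, flipped)$r, -1, tolerance = 1e-12)
})

test_that("shared age effects give concordant Z scores across sample groups", {
  co <- default_cohort()
  # the middle and old age groups share the planted age effects, but the old
  # group is small (~10% of samples), so concordance is positive yet modest
  ew <- stratify_ewas(co$beta, co$samples, groups = ewas_age_groups()[2:3, ])
  conc <- crossgroup_concordance(dplyr::filter(ew, .data$group == "middle"),
                                 dplyr::filter(ew, .data$group == "old"))
  expect_gt(conc$r, 0.2)
  # two equal-powered halves of the same ages recover the shared signal
  # with high concordance
  mid <- which(co$samples$age >= 40 & co$samples$age < 90)
  h1 <- mid[seq_along(mid) %% 2 == 1]
  h2 <- mid[seq_along(mid) %% 2 == 0]
  ew1 <- correlate_cpgs_age(co$beta[, h1], co$samples$age[h1], "half1")
  ew2 <- correlate_cpgs_age(co$beta[, h2], co$samples$age[h2], "half2")
  expect_gt(crossgroup_concordance(ew1, ew2)$r, 0.5)
})

test_that("Manhattan export flags genome-wide hits strictly below 1e-7", {
  ann <- tibble::tibble(cpg_id = c("cg1", "cg2", "cg3"),
                        chrom = c("chr1", "chr2", "chr3"),
                        start = c(100L, 200L, 300L), end = c(102L, 202L, 302L),
                        gene = c("A", "B", "C"))
  ew <- tibble::tibble(cpg_id = c("cg1", "cg2", "cg3", "cg4"),
                       group = "old", n = 50,
                       r = c(0.9, 0.5, -0.4, 0.1),
                       z = c(6, 5, -4, 1),
                       log10_p = c(-8, -7, -3, -1))
  class(ew) <- c("ewas_result", class(ew))
  expect_message(man <- export_manhattan(ew, ann), "1 CpGs without annotation")
  expect_equal(man$genomewide_flag, c(TRUE, FALSE, FALSE))  # 1e-7 exactly: FALSE
  expect_equal(man$minus_log10_p, c(8, 7, 3))
  # round-trip through the TSV writer/reader
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(man, path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(as.data.frame(back), as.data.frame(man), tolerance = 1e-12)
})

test_that("null CpGs keep the nominal type-I error rate", {
  # 20 seeded replicates of 2000 independent null CpGs at n = 344
  rates <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    beta <- matrix(rbinom(2000 * 344, 1, 0.5), 2000, 344,
                   dimnames = list(sprintf("cg%04d", 1:2000),
                                   sprintf("S%03d", 1:344)))
    ages <- runif(344, 0, 40)
    ew <- correlate_cpgs_age(beta, ages)
    mean(10^ew$log10_p < 0.05, na.rm = TRUE)
  }, numeric(1))
  expect_gte(mean(rates), 0.03)
  expect_lte(mean(rates), 0.07)
})
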