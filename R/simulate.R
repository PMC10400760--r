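#' Configuration for the synthetic methylome cohort generator
#'
#' Bundles every knob of the cohort simulator with defaults calibrated once to
#' the marginals of a large multi-cohort blood/saliva training set: a 40-115
#' year age range whose 100+ tail holds about 2.6% of samples (mean ~105.6,
#' SD ~3.5 within the tail), ~55% female, a handful of source cohorts with
#' small additive batch effects, age-correlated CpGs with linear and
#' saturating mean trajectories, residual noise whose SD grows with age, a
#' mortality hazard multiplied by ~1.05 per year of epigenetic age
#' acceleration, and biomarkers with weak (|bicor| 0.04-0.17) associations.
#'
#' @param n_samples Number of samples.
#' @param n_cpgs Number of CpGs (including the sex-linked block).
#' @param frac_pos_linear,frac_neg_linear,frac_saturating,frac_null Fractions
#'   of the non-sex-linked CpGs in each trajectory class; must sum to 1.
#' @param age_range Numeric length-2, minimum and maximum age in years.
#' @param centenarian_frac Fraction of samples with age >= 100.
#' @param female_frac Fraction of female samples.
#' @param n_cohorts Number of source cohorts (batch labels).
#' @param batch_sd SD (beta scale) of per-(cohort, CpG) additive offsets.
#' @param noise_sd_base,noise_sd_age_slope Residual SD at age 0 and its
#'   per-year increase; the SD at age a is `noise_sd_base + noise_sd_age_slope * a`.
#' @param effect_slope_range Length-2 magnitude range (per year, beta scale)
#'   for the slopes of causal CpGs.
#' @param n_sex_linked Number of CpGs whose mean is offset by sex.
#' @param sex_effect Mean beta offset of sex-linked CpGs in females.
#' @param state_enrichment_odds Odds multiplier with which positively
#'   age-related CpGs are preferentially placed into bivalent/PRC2 chromatin
#'   states, so enrichment is recoverable by construction.
#' @param baseline_hazard Baseline mortality hazard (per year) at the
#'   reference age of 70.
#' @param hr_per_year_accel Multiplicative hazard per year of age acceleration.
#' @param hr_per_year_age Multiplicative hazard per year of chronological age.
#' @param follow_up Administrative censoring time in years.
#' @param accel_sd SD (years) of the latent age-acceleration of each sample.
#' @param n_biomarkers Number of simulated biomarkers.
#' @param biomarker_bicor_range Length-2 magnitude range of the planted
#'   biomarker associations with age acceleration (signs alternate).
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the configuration including this seed.
#'
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_samples = 50, n_cpgs = 100, seed = 1)
#' cohort <- simulate_cohort(cfg)
#' dim(cohort$beta)
sim_config <- function(n_samples = 600,
                       n_cpgs = 2000,
                       frac_pos_linear = 0.10,
                       frac_neg_linear = 0.10,
                       frac_saturating = 0.05,
                       frac_null = 0.75,
                       age_range = c(40, 115),
                       centenarian_frac = 184 / 7039,
                       female_frac = 0.545,
                       n_cohorts = 3,
                       batch_sd = 0.01,
                       noise_sd_base = 0.02,
                       noise_sd_age_slope = 5e-4,
                       effect_slope_range = c(0.001, 0.003),
                       n_sex_linked = 50,
                       sex_effect = 0.15,
                       state_enrichment_odds = 5,
                       baseline_hazard = 0.01,
                       hr_per_year_accel = 1.05,
                       hr_per_year_age = 1.08,
                       follow_up = 15,
                       accel_sd = 3,
                       n_biomarkers = 4,
                       biomarker_bicor_range = c(0.04, 0.17),
                       seed = 1L) {
  cfg <- list(
    n_samples = as.integer(n_samples), n_cpgs = as.integer(n_cpgs),
    frac_pos_linear = frac_pos_linear, frac_neg_linear = frac_neg_linear,
    frac_saturating = frac_saturating, frac_null = frac_null,
    age_range = age_range, centenarian_frac = centenarian_frac,
    female_frac = female_frac, n_cohorts = as.integer(n_cohorts),
    batch_sd = batch_sd, noise_sd_base = noise_sd_base,
    noise_sd_age_slope = noise_sd_age_slope,
    effect_slope_range = effect_slope_range,
    n_sex_linked = as.integer(n_sex_linked), sex_effect = sex_effect,
    state_enrichment_odds = state_enrichment_odds,
    baseline_hazard = baseline_hazard,
    hr_per_year_accel = hr_per_year_accel,
    hr_per_year_age = hr_per_year_age, follow_up = follow_up,
    accel_sd = accel_sd, n_biomarkers = as.integer(n_biomarkers),
    biomarker_bicor_range = biomarker_bicor_range, seed = as.integer(seed)
  )
  fr <- c(cfg$frac_pos_linear, cfg$frac_neg_linear, cfg$frac_saturating, cfg$frac_null)
  stop_if(any(fr < 0 | fr > 1), "class fractions must lie in [0, 1]")
  stop_if(abs(sum(fr) - 1) > 1e-12, "class fractions must sum to 1")
  stop_if(cfg$centenarian_frac < 0 || cfg$centenarian_frac > 1,
          "centenarian_frac must lie in [0, 1]")
  stop_if(cfg$female_frac < 0 || cfg$female_frac > 1, "female_frac must lie in [0, 1]")
  stop_if(length(cfg$age_range) != 2 || cfg$age_range[1] >= cfg$age_range[2],
          "age_range must be increasing [min, max]")
  stop_if(cfg$noise_sd_base <= 0, "noise_sd_base must be > 0")
  stop_if(cfg$noise_sd_age_slope < 0, "noise_sd_age_slope must be >= 0")
  stop_if(cfg$n_sex_linked >= cfg$n_cpgs, "n_sex_linked must be < n_cpgs")
  structure(cfg, class = "sim_config")
}

# universal-chromatin-state-style labels used by the toy annotation;
# the first three are the designated bivalent/PRC2 target states
sim_states <- function() {
  c("BivProm1", "BivProm2", "ReprPC1", "PromF2", "EnhA1", "EnhA2",
    "TxEx4", "TSS1", "Quies1", "GapArtf1")
}

#' Mean methylation trajectory of a simulated CpG
#'
#' The noiseless mean beta of a CpG at a given age under its trajectory class:
#' linear classes follow `baseline + slope * age`; saturating CpGs are linear
#' until `saturation_age` and constant after; null (and sex-linked) CpGs sit
#' at their baseline. All means are clamped to `[0, 1]`.
#'
#' @param spec A one-row data frame (or list) with fields `class_label`,
#'   `baseline_beta`, `slope`, `saturation_age`.
#' @param age Age in years (vectorized), must be >= 0.
#' @return Mean beta value(s) in `[0, 1]`.
#' @export
mean_trajectory <- function(spec, age) {
  stop_if(any(age < 0), "age must be >= 0")
  cls <- as.character(spec$class_label)
  stop_if(!cls %in% c("pos_linear", "neg_linear", "saturating", "null", "sex_linked"),
          paste0("unknown class_label: ", cls))
  mu <- switch(cls,
    pos_linear = spec$baseline_beta + spec$slope * age,
    neg_linear = spec$baseline_beta + spec$slope * age,
    saturating = spec$baseline_beta + spec$slope * pmin(age, spec$saturation_age),
    null = rep(spec$baseline_beta, length(age)),
    sex_linked = rep(spec$baseline_beta, length(age))
  )
  clamp01(mu)
}

# draw ages: uniform body on [min, 95] plus a shifted-exponential 100+ tail
draw_ages <- function(n, age_range, centenarian_frac) {
  n_cen <- round(n * centenarian_frac)
  body_hi <- min(95, age_range[2])
  body <- runif(n - n_cen, age_range[1], body_hi)
  tail <- 100 + rexp(n_cen, rate = 1 / 5.6)
  while (any(tail > age_range[2])) {
    bad <- tail > age_range[2]
    tail[bad] <- 100 + rexp(sum(bad), rate = 1 / 5.6)
  }
  sample(c(body, tail))  # shuffle so centenarians are not a contiguous block
}

# build the per-CpG ground-truth table (class, baseline, slope, annotation)
build_cpg_spec <- function(cfg) {
  n_core <- cfg$n_cpgs - cfg$n_sex_linked
  counts <- round(n_core * c(cfg$frac_pos_linear, cfg$frac_neg_linear,
                             cfg$frac_saturating, cfg$frac_null))
  counts[4] <- n_core - sum(counts[1:3])
  stop_if(counts[4] < 0, "n_cpgs too small for the requested class fractions")
  classes <- c(rep("pos_linear", counts[1]), rep("neg_linear", counts[2]),
               rep("saturating", counts[3]), rep("null", counts[4]),
               rep("sex_linked", cfg$n_sex_linked))
  n <- cfg$n_cpgs
  stop_if(n < 5, "n_cpgs must cover at least one CpG per class")
  slope_mag <- runif(n, cfg$effect_slope_range[1], cfg$effect_slope_range[2])
  slope <- ifelse(classes == "neg_linear", -slope_mag,
                  ifelse(classes %in% c("pos_linear", "saturating"), slope_mag, 0))
  amax <- cfg$age_range[2]
  baseline <- runif(n, 0.35, 0.65)
  span <- abs(slope) * amax
  baseline[classes %in% c("pos_linear", "saturating")] <-
    runif(sum(classes %in% c("pos_linear", "saturating")), 0.05, 0.30)
  baseline[classes == "neg_linear"] <-
    runif(sum(classes == "neg_linear"), 0.70, 0.95)
  # keep the whole mean trajectory inside [0.02, 0.98] over the age range
  baseline <- pmin(pmax(baseline, ifelse(slope < 0, span + 0.02, 0.02)),
                   ifelse(slope > 0, 0.98 - span, 0.98))
  saturation_age <- runif(n, 55, 75)

  states <- sim_states()
  target <- states[1:3]  # bivalent/PRC2-like states
  base_w <- setNames(rep(1, length(states)), states)
  w_mat <- matrix(rep(base_w, n), nrow = n, byrow = TRUE,
                  dimnames = list(NULL, states))
  w_mat[classes == "pos_linear", target] <- cfg$state_enrichment_odds
  state <- vapply(seq_len(n), function(i)
    sample(states, 1, prob = w_mat[i, ]), character(1))

  # PRC member binding: frequent in bivalent/PRC2-like states, rare elsewhere
  in_target <- state %in% target
  p2 <- ifelse(in_target, 0.8, 0.08)
  p1 <- ifelse(in_target, 0.25, 0.03)
  draw_members <- function(p) matrix(rbinom(3 * n, 1, rep(p, each = 3)),
                                     nrow = n, byrow = TRUE)
  prc1_m <- draw_members(p1)
  prc2_m <- draw_members(p2)

  tibble::tibble(
    cpg_id = sprintf("cg%07d", seq_len(n)),
    class_label = classes,
    baseline_beta = baseline,
    slope = slope,
    saturation_age = saturation_age,
    chrom = paste0("chr", 1 + (seq_len(n) - 1) %% 22),
    pos = 1000L + 100L * seq_len(n),
    gene = sprintf("GENE%04d", 1 + (seq_len(n) - 1) %/% 5),
    state = state,
    RING1 = prc1_m[, 1], RNF2 = prc1_m[, 2], BMI1 = prc1_m[, 3],
    EED = prc2_m[, 1], SUZ12 = prc2_m[, 2], EZH2 = prc2_m[, 3]
  )
}

#' Simulate an aging methylome cohort
#'
#' Generates a beta-value matrix (CpGs x samples), a sample sheet with ages,
#' sex, cohort labels, survival follow-up and biomarkers, a BED-like CpG
#' annotation (chromatin state + PRC member binding), and the ground-truth
#' per-CpG specification. Mean trajectories follow [mean_trajectory()];
#' residual noise is truncated Gaussian on the beta scale with SD growing
#' linearly in age; cohorts add small per-(cohort, CpG) offsets; a sex-linked
#' CpG block is offset in females. Each sample carries a latent age
#' acceleration that drives both its survival times (via
#' [simulate_survival()]) and its biomarkers (via [simulate_biomarkers()]).
#'
#' @param config A [sim_config()].
#' @return A list of class `methylome_cohort` with elements `beta` (matrix),
#'   `samples` (tibble sample sheet; includes the latent `true_accel`),
#'   `annotation` (tibble), `cpg_spec` (tibble) and `config`.
#' @export
simulate_cohort <- function(config) {
  stop_if(!inherits(config, "sim_config"), "`config` must come from sim_config()")
  cfg <- config
  set.seed(cfg$seed)

  spec <- build_cpg_spec(cfg)
  n <- cfg$n_samples
  age <- draw_ages(n, cfg$age_range, cfg$centenarian_frac)
  sex <- ifelse(runif(n) < cfg$female_frac, "F", "M")
  cohort_lab <- paste0("cohort", sample.int(cfg$n_cohorts, n, replace = TRUE))
  sample_id <- sprintf("S%05d", seq_len(n))

  # mean trajectories, vectorized over CpGs x samples
  mu <- matrix(spec$baseline_beta, nrow = nrow(spec), ncol = n)
  eff_age <- outer(rep(1, nrow(spec)), age)
  sat <- spec$class_label == "saturating"
  eff_age[sat, ] <- pmin(eff_age[sat, , drop = FALSE], spec$saturation_age[sat])
  lin <- spec$class_label %in% c("pos_linear", "neg_linear", "saturating")
  mu[lin, ] <- mu[lin, ] + spec$slope[lin] * eff_age[lin, , drop = FALSE]
  sexed <- spec$class_label == "sex_linked"
  mu[sexed, sex == "F"] <- mu[sexed, sex == "F"] + cfg$sex_effect

  batch <- matrix(rnorm(nrow(spec) * cfg$n_cohorts, 0, cfg$batch_sd),
                  nrow = nrow(spec))
  mu <- mu + batch[, match(cohort_lab, paste0("cohort", seq_len(cfg$n_cohorts)))]

  noise_sd <- cfg$noise_sd_base + cfg$noise_sd_age_slope * age
  noise <- matrix(rnorm(nrow(spec) * n), nrow = nrow(spec)) *
    rep(noise_sd, each = nrow(spec))
  beta <- clamp01(mu + noise)
  dimnames(beta) <- list(spec$cpg_id, sample_id)

  true_accel <- rnorm(n, 0, cfg$accel_sd)
  surv <- simulate_survival(true_accel, cfg$baseline_hazard,
                            cfg$hr_per_year_accel, cfg$follow_up,
                            seed = derive_seed(cfg$seed, "survival"),
                            age = age, hr_per_year_age = cfg$hr_per_year_age)
  targets <- biomarker_targets(cfg$n_biomarkers, cfg$biomarker_bicor_range)
  biom <- simulate_biomarkers(true_accel, targets,
                              seed = derive_seed(cfg$seed, "biomarkers"))

  samples <- tibble::tibble(
    sample_id = sample_id, age = age, sex = sex, cohort = cohort_lab,
    tissue = "blood", time = surv$time, event = surv$event,
    true_accel = true_accel
  )
  samples <- dplyr::bind_cols(samples, biom)

  annotation <- spec %>%
    dplyr::mutate(start = .data$pos, end = .data$pos + 2L) %>%
    dplyr::select("chrom", "start", "end", "cpg_id", "gene", "state",
                  "RING1", "RNF2", "BMI1", "EED", "SUZ12", "EZH2")
  annotation <- dplyr::bind_cols(annotation,
                                 prc_flags(annotation)[, c("prc1", "prc2")])

  structure(list(beta = beta, samples = samples, annotation = annotation,
                 cpg_spec = spec, config = cfg),
            class = "methylome_cohort")
}

#' @export
print.methylome_cohort <- function(x, ...) {
  cat(sprintf("<methylome_cohort> %d CpGs x %d samples, ages %.1f-%.1f (%d aged 100+)\n",
              nrow(x$beta), ncol(x$beta), min(x$samples$age), max(x$samples$age),
              sum(x$samples$age >= 100)))
  invisible(x)
}

# alternating-sign magnitudes spanning the configured bicor range
biomarker_targets <- function(n, rng) {
  if (n == 0) return(numeric(0))
  mags <- seq(rng[2], rng[1], length.out = n)
  mags * rep_len(c(-1, 1), n)
}

#' Simulate survival times driven by epigenetic age acceleration
#'
#' Exponential event times with per-sample hazard
#' `baseline_hazard * hr_per_year^age_accel` (optionally also scaled by
#' `hr_per_year_age^(age - 70)`), administratively censored at `follow_up`
#' years.
#'
#' @param age_accel Numeric vector, age acceleration in years.
#' @param baseline_hazard Baseline hazard per year (> 0).
#' @param hr_per_year Multiplicative hazard per year of acceleration (> 0).
#' @param follow_up Censoring horizon in years (> 0).
#' @param seed Integer seed.
#' @param age Optional chronological ages used with `hr_per_year_age`.
#' @param hr_per_year_age Multiplicative hazard per year of age (default 1 =
#'   no age effect).
#' @return A tibble with `time` (years) and `event` (1 = death, 0 = censored).
#' @export
simulate_survival <- function(age_accel, baseline_hazard, hr_per_year,
                              follow_up, seed = 1L, age = NULL,
                              hr_per_year_age = 1) {
  stop_if(any(!is.finite(age_accel)), "age_accel must be finite")
  stop_if(baseline_hazard <= 0, "baseline_hazard must be > 0")
  stop_if(hr_per_year <= 0, "hr_per_year must be > 0")
  stop_if(follow_up <= 0,
          "follow_up must be > 0 (0 would censor every record at time 0)")
  set.seed(seed)
  hz <- baseline_hazard * hr_per_year^age_accel
  if (!is.null(age)) hz <- hz * hr_per_year_age^(age - 70)
  t_event <- rexp(length(age_accel), rate = hz)
  tibble::tibble(time = pmin(t_event, follow_up),
                 event = as.integer(t_event <= follow_up))
}

#' Simulate biomarkers with planted associations to age acceleration
#'
#' Each biomarker is `target * scale(age_accel) + sqrt(1 - target^2) * noise`,
#' giving (in expectation) the requested correlation with acceleration.
#'
#' @param age_accel Numeric vector of age accelerations (years).
#' @param targets Numeric vector of target correlation magnitudes, each with
#'   `|target| < 1`.
#' @param seed Integer seed.
#' @return A tibble with one `biomarker_*` column per target.
#' @export
simulate_biomarkers <- function(age_accel, targets, seed = 1L) {
  stop_if(any(abs(targets) >= 1), "|target| must be < 1 for every biomarker")
  set.seed(seed)
  z <- as.numeric(scale(age_accel))
  cols <- lapply(seq_along(targets), function(j) {
    targets[j] * z + sqrt(1 - targets[j]^2) * rnorm(length(z))
  })
  names(cols) <- sprintf("biomarker_%02d", seq_along(targets))
  tibble::as_tibble(if (length(cols)) cols else list())
}

#' Write a simulated cohort to plain-text artifacts
#'
#' Beta matrix as TSV (first column `cpg_id`), sample sheet as CSV, annotation
#' as BED-like TSV (0-based half-open), and the ground-truth CpG spec as TSV.
#'
#' @param cohort A `methylome_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(beta = file.path(dir, "beta.tsv"),
             samples = file.path(dir, "samples.csv"),
             annotation = file.path(dir, "annotation.tsv"),
             cpg_spec = file.path(dir, "cpg_spec.tsv"))
  beta_df <- tibble::as_tibble(cohort$beta, rownames = "cpg_id")
  readr::write_tsv(beta_df, paths["beta"])
  readr::write_csv(cohort$samples, paths["samples"])
  readr::write_tsv(cohort$annotation, paths["annotation"])
  readr::write_tsv(cohort$cpg_spec, paths["cpg_spec"])
  invisible(paths)
}

#' Read a beta matrix written by [write_cohort()]
#' @param path TSV file whose first column is `cpg_id`.
#' @return A numeric matrix, CpGs x samples.
#' @export
read_beta_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  m
}
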