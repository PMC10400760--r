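# End-to-end scenario runner: simulate -> clean -> prefilter -> train ->
# crossval -> ageaccel -> ewas -> enrich -> assoc -> trajectories, with a
# machine-readable manifest and full seed determinism.

pipeline_stage_names <- function() {
  c("simulate", "clean", "prefilter", "train", "crossval", "ageaccel",
    "ewas", "enrich", "assoc", "trajectories")
}

#' Pipeline configuration
#'
#' Declarative configuration for [run_scenario()]. Unknown keys — top level
#' or inside a block — are errors, not warnings, so misspelled settings never
#' pass silently. The single `seed` drives every stage (each stage derives
#' its own child seed deterministically).
#'
#' @param sim A [sim_config()] (or argument list for it).
#' @param stages Character vector of stages to run, in pipeline order.
#' @param prefilter List: `n_pos`, `n_neg`, `n_null`, `eps_null`.
#' @param clean List: `abs_resid_years`, `max_iter`.
#' @param clock List: `kind`, `train_age_min`, `centenarian_weight`, `alpha`,
#'   `nlambda`, `cv_folds`.
#' @param crossval List: `n_folds`.
#' @param ewas List: `groups` (tibble as [ewas_age_groups()]).
#' @param enrich List: `top_k`.
#' @param assoc List: `strata` (stratum column), `variables` (NULL = every
#'   `biomarker_*` column).
#' @param trajectories List: `targets` (NULL = top EWAS CpG + every state
#'   present), `frac`.
#' @param seed Global integer seed (overrides the one in `sim`).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            stages = pipeline_stage_names(),
                            prefilter = list(),
                            clean = list(),
                            clock = list(),
                            crossval = list(),
                            ewas = list(),
                            enrich = list(),
                            assoc = list(),
                            trajectories = list(),
                            seed = 1L) {
  if (!inherits(sim, "sim_config")) sim <- do.call(sim_config, sim)
  unknown <- setdiff(stages, pipeline_stage_names())
  stop_if(length(unknown) > 0,
          paste0("unknown stage name(s): ", paste(unknown, collapse = ", ")))
  merge_block <- function(defaults, user, block) {
    bad <- setdiff(names(user), names(defaults))
    stop_if(length(bad) > 0,
            paste0("unknown key(s) in `", block, "`: ",
                   paste(bad, collapse = ", ")))
    modifyList(defaults, user)
  }
  cfg <- list(
    sim = sim,
    stages = stages,
    prefilter = merge_block(list(n_pos = 100, n_neg = 100, n_null = 50,
                                 eps_null = 0.05), prefilter, "prefilter"),
    clean = merge_block(list(abs_resid_years = 30, max_iter = 3),
                        clean, "clean"),
    clock = merge_block(list(kind = "elastic_net", train_age_min = 40,
                             centenarian_weight = 10, alpha = 0.5,
                             nlambda = 50, cv_folds = 10), clock, "clock"),
    crossval = merge_block(list(n_folds = 20), crossval, "crossval"),
    ewas = merge_block(list(groups = ewas_age_groups()), ewas, "ewas"),
    enrich = merge_block(list(top_k = 100), enrich, "enrich"),
    assoc = merge_block(list(strata = "cohort", variables = NULL),
                        assoc, "assoc"),
    trajectories = merge_block(list(targets = NULL, frac = 2/3),
                               trajectories, "trajectories"),
    seed = as.integer(seed)
  )
  cfg$sim$seed <- derive_seed(cfg$seed, "simulate")
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' The YAML mirrors the blocks of [pipeline_config()]; unknown keys are
#' errors.
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("sim", "stages", "prefilter", "clean", "clock", "crossval",
             "ewas", "enrich", "assoc", "trajectories", "seed")
  bad <- setdiff(names(raw), known)
  stop_if(length(bad) > 0,
          paste0("unknown key(s) in config file: ", paste(bad, collapse = ", ")))
  do.call(pipeline_config, raw)
}

log_stage <- function(stage, msg) {
  rlang::inform(sprintf("[%s] %s: %s",
                        format(Sys.time(), "%H:%M:%S"), stage, msg))
}

#' Run the end-to-end demonstration scenario
#'
#' Strings together the full analysis on a simulated cohort and writes every
#' stage's artifact (TSV/CSV/JSON) plus `manifest.csv` recording, per
#' artifact, the producing stage, its seed, md5 hash, and runtime. Rerunning
#' with an identical configuration reproduces identical artifact hashes.
#'
#' @param config A [pipeline_config()] (or path to a YAML file).
#' @param out_dir Output directory.
#' @return Invisibly, the manifest tibble.
#' @export
run_scenario <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stop_if(!inherits(config, "pipeline_config"),
          "`config` must come from pipeline_config()")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  state <- new.env(parent = emptyenv())

  record <- function(stage, paths, t0) {
    rel <- unname(vapply(paths, function(p) {
      if (startsWith(p, paste0(out_dir, "/")))
        substring(p, nchar(out_dir) + 2) else basename(p)
    }, character(1)))
    manifest[[stage]] <<- tibble::tibble(
      stage = stage, artifact = rel,
      md5 = unname(tools::md5sum(unname(paths))),
      seed = derive_seed(config$seed, stage),
      runtime_s = round(as.numeric(Sys.time()) - t0, 3))
  }

  runners <- list(
    simulate = function() {
      state$cohort <- simulate_cohort(config$sim)
      write_cohort(state$cohort, out_dir)
      c(file.path(out_dir, c("beta.tsv", "samples.csv", "annotation.tsv",
                             "cpg_spec.tsv")))
    },
    clean = function() {
      res <- remove_outliers(state$cohort$beta, state$cohort$samples,
                             abs_resid_years = config$clean$abs_resid_years,
                             max_iter = config$clean$max_iter)
      state$beta <- state$cohort$beta[, res$kept_ids, drop = FALSE]
      state$samples <- state$cohort$samples[
        match(res$kept_ids, state$cohort$samples$sample_id), ]
      log_stage("clean", sprintf("%d of %d samples kept (threshold %g years)",
                                 length(res$kept_ids), ncol(state$cohort$beta),
                                 config$clean$abs_resid_years))
      p <- file.path(out_dir, "outlier_report.csv")
      readr::write_csv(res$report, p)
      p
    },
    prefilter = function() {
      pf <- do.call(prefilter_cpgs,
                    c(list(beta = state$beta, ages = state$samples$age),
                      config$prefilter))
      state$prefilter <- pf
      state$beta_sel <- state$beta[selected_cpgs(pf), , drop = FALSE]
      p <- file.path(out_dir, "prefilter.tsv")
      readr::write_tsv(dplyr::mutate(
        pf$r_by_cpg,
        set = dplyr::case_when(.data$cpg_id %in% pf$pos_set ~ "pos",
                               .data$cpg_id %in% pf$neg_set ~ "neg",
                               .data$cpg_id %in% pf$null_set ~ "null",
                               TRUE ~ "unselected")), p)
      p
    },
    train = function() {
      ck <- config$clock
      state$model <- train_clock(
        state$beta_sel, state$samples, kind = ck$kind,
        train_age_min = ck$train_age_min,
        centenarian_weight = ck$centenarian_weight, alpha = ck$alpha,
        nlambda = ck$nlambda, cv_folds = ck$cv_folds,
        seed = derive_seed(config$seed, "train"))
      log_stage("train", sprintf(
        "%s clock, %d features, centenarian weight %g",
        ck$kind, length(state$model$coefficients), ck$centenarian_weight))
      write_clock(state$model, file.path(out_dir, "clock"))
      file.path(out_dir, "clock",
                c("clock.json",
                  if (ck$kind == "elastic_net") "coefficients.csv"))
    },
    crossval = function() {
      ck <- config$clock
      builder <- function(b, s) train_clock(
        b, s, kind = ck$kind, train_age_min = ck$train_age_min,
        centenarian_weight = ck$centenarian_weight, alpha = ck$alpha,
        nlambda = ck$nlambda, cv_folds = ck$cv_folds,
        seed = derive_seed(config$seed, "train"))
      cv <- crossvalidate_20fold(state$beta_sel, state$samples, builder,
                                 n_folds = config$crossval$n_folds,
                                 seed = derive_seed(config$seed, "crossval"))
      state$cv <- cv
      p1 <- file.path(out_dir, "crossval_oof.csv")
      p2 <- file.path(out_dir, "crossval_metrics.csv")
      readr::write_csv(cv$oof, p1)
      readr::write_csv(cv$metrics, p2)
      c(p1, p2)
    },
    ageaccel = function() {
      pred <- predict_age(state$model, state$beta_sel)
      acc <- compute_age_accel(pred$dnam_age, state$samples$age,
                               state$samples$sample_id)
      state$accel <- acc
      p <- file.path(out_dir, "age_accel.csv")
      readr::write_csv(acc, p)
      p
    },
    ewas = function() {
      ew <- stratify_ewas(state$beta, state$samples,
                          groups = config$ewas$groups)
      state$ewas <- ew
      p1 <- file.path(out_dir, "ewas.tsv")
      readr::write_tsv(ew, p1)
      grp <- unique(ew$group)[1]
      man <- export_manhattan(dplyr::filter(ew, .data$group == grp),
                              state$cohort$annotation)
      p2 <- file.path(out_dir, "manhattan.tsv")
      readr::write_tsv(man, p2)
      c(p1, p2)
    },
    enrich = function() {
      grp <- dplyr::filter(state$ewas,
                           .data$group == dplyr::last(unique(state$ewas$group)))
      k <- min(config$enrich$top_k, sum(grp$z > 0, na.rm = TRUE),
               sum(grp$z < 0, na.rm = TRUE))
      res <- dplyr::bind_rows(
        enrich_states(top_k_cpgs(grp, k, "positive"),
                      state$cohort$annotation, set_label = "top_positive"),
        enrich_states(top_k_cpgs(grp, k, "negative"),
                      state$cohort$annotation, set_label = "top_negative"))
      state$enrich <- res
      p1 <- file.path(out_dir, "enrichment.tsv")
      p2 <- file.path(out_dir, "enrichment_matrix.tsv")
      readr::write_tsv(res, p1)
      readr::write_tsv(signed_log10p_matrix(res), p2)
      c(p1, p2)
    },
    assoc = function() {
      vars <- config$assoc$variables %||%
        grep("^biomarker_", names(state$samples), value = TRUE)
      df <- dplyr::left_join(state$samples, state$accel, by = "sample_id")
      tab <- stratified_bicor_meta(df, accel = "accel", variables = vars,
                                   strata = config$assoc$strata)
      mort <- mortality_meta(df, accel = "accel",
                             covariates = c("age", "sex"),
                             strata = config$assoc$strata)
      p1 <- file.path(out_dir, "biomarker_assoc.tsv")
      p2 <- file.path(out_dir, "mortality.tsv")
      readr::write_tsv(tab, p1)
      readr::write_tsv(mort, p2)
      c(p1, p2)
    },
    trajectories = function() {
      targets <- config$trajectories$targets %||% {
        grp <- dplyr::filter(state$ewas,
                             .data$group == unique(state$ewas$group)[1])
        top_cpg <- top_k_cpgs(grp, 1, "positive")
        c(top_cpg, sort(unique(state$cohort$annotation$state))[1:2], "PRC2")
      }
      tr <- trajectory_report(state$beta, state$samples, targets,
                              annotation = state$cohort$annotation,
                              frac = config$trajectories$frac)
      p1 <- file.path(out_dir, "trajectory_report.tsv")
      p2 <- file.path(out_dir, "trajectory_curves.tsv")
      readr::write_tsv(tr$report, p1)
      readr::write_tsv(tr$curves, p2)
      c(p1, p2)
    }
  )

  for (stage in config$stages) {
    t0 <- as.numeric(Sys.time())
    log_stage(stage, "running")
    paths <- tryCatch(runners[[stage]](), error = function(e)
      rlang::abort(paste0("stage '", stage, "' failed: ",
                          conditionMessage(e)), parent = e))
    record(stage, paths, t0)
  }
  manifest <- dplyr::bind_rows(manifest)
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
  invisible(manifest)
}

#' Out-of-distribution calibration analysis
#'
#' Trains a clock on a restricted age interval and reports the mean signed
#' residual (predicted minus chronological age) within disjoint evaluation
#' intervals — the standard demonstration that clocks trained on younger
#' ranges stay calibrated near their training window but underestimate in
#' older individuals (regression to the mean).
#'
#' @param cohort A `methylome_cohort` (or a list with `beta` and `samples`).
#' @param train_interval Length-2 training age interval (bounds inclusive).
#' @param eval_intervals List of length-2 evaluation intervals; must not
#'   overlap the training interval.
#' @param centenarian_weight Weight for samples aged >= 100 during training.
#' @param prefilter Prefilter settings (list as in [pipeline_config()]).
#' @param seed Integer seed.
#' @return A tibble `interval`, `n`, `mean_residual_years` (NA when the
#'   interval holds no samples).
#' @export
out_of_distribution_scenario <- function(cohort,
                                         train_interval = c(40, 90),
                                         eval_intervals = list(c(100, 115)),
                                         centenarian_weight = 1,
                                         prefilter = list(n_pos = 100,
                                                          n_neg = 100,
                                                          n_null = 50,
                                                          eps_null = 0.05),
                                         seed = 1L) {
  for (iv in eval_intervals)
    stop_if(iv[1] <= train_interval[2] && train_interval[1] <= iv[2],
            "evaluation intervals must not overlap the training interval")
  beta <- cohort$beta
  sheet <- cohort$samples
  tr <- sheet$age >= train_interval[1] & sheet$age <= train_interval[2]
  pf <- do.call(prefilter_cpgs,
                c(list(beta = beta[, tr, drop = FALSE],
                       ages = sheet$age[tr]), prefilter))
  model <- train_clock(beta[selected_cpgs(pf), tr, drop = FALSE],
                       sheet[tr, , drop = FALSE],
                       kind = "elastic_net", train_age_min = 0,
                       centenarian_weight = centenarian_weight, seed = seed)
  pred <- predict_age(model, beta[selected_cpgs(pf), , drop = FALSE])
  resid <- pred$dnam_age - sheet$age
  purrr::map(c(list(train_interval), eval_intervals), function(iv) {
    sel <- sheet$age >= iv[1] & sheet$age <= iv[2]
    tibble::tibble(interval = sprintf("[%g, %g]", iv[1], iv[2]),
                   n = sum(sel),
                   mean_residual_years = if (any(sel)) mean(resid[sel])
                   else NA_real_)
  }) %>% dplyr::bind_rows()
}
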