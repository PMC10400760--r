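# small simulated cohorts shared across test files, built once per run

small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_cohort(sim_config(n_samples = 200, n_cpgs = 400,
                                           seed = 11L))
    cache
  }
})

# default-scale cohort used by recovery tests (n = 600, 2000 CpGs)
default_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_cohort(sim_config(seed = 7L))
    cache
  }
})

# deterministic toy matrix with known age relationships
toy_beta <- function(ages = c(40, 55, 62, 70, 85, 100)) {
  beta <- rbind(
    cgA = ages / 120,            # strictly increasing with age
    cgB = 1 - ages / 120,        # strictly decreasing
    cgC = rep(0.5, length(ages)) + c(0.01, -0.01, 0, 0.01, -0.01, 0)
  )
  colnames(beta) <- paste0("S", seq_along(ages))
  beta
}

toy_sheet <- function(ages = c(40, 55, 62, 70, 85, 100)) {
  tibble::tibble(sample_id = paste0("S", seq_along(ages)), age = ages)
}
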