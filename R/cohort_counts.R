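# Printed marginals of the reference multi-cohort training data: per age
# stratum, the sample count and the female/tissue counts. These are the
# emulation targets the simulator defaults are calibrated to.

#' Reference training-cohort summary counts
#'
#' Per-age-stratum sample counts (total, female, and per tissue) of the
#' multi-cohort blood/saliva training data whose structure the simulator
#' emulates.
#'
#' @return A tibble `stratum`, `n`, `n_female`, `n_blood`, `n_saliva`,
#'   `n_buccal`, `n_urine`.
#' @export
reference_cohort_counts <- function() {
  readr::read_tsv(system.file("extdata", "reference_cohort_counts.tsv",
                              package = "centclock"),
                  show_col_types = FALSE)
}

#' Percentage summaries of cohort count tables
#'
#' Recomputes the percentage columns (female and tissue shares, and each
#' stratum's share of the 40+ total) from raw counts.
#'
#' @param counts A counts tibble as from [reference_cohort_counts()].
#' @return A tibble with `stratum`, `female_pct`, `blood_pct`, `saliva_pct`,
#'   `buccal_pct`, `of_40plus_pct`.
#' @export
cohort_percentages <- function(counts = reference_cohort_counts()) {
  total_40plus <- counts$n[counts$stratum == "age_40plus"]
  counts %>%
    dplyr::mutate(
      female_pct = 100 * .data$n_female / .data$n,
      blood_pct = 100 * .data$n_blood / .data$n,
      saliva_pct = 100 * .data$n_saliva / .data$n,
      buccal_pct = 100 * .data$n_buccal / .data$n,
      of_40plus_pct = 100 * .data$n / total_40plus
    ) %>%
    dplyr::select("stratum", "female_pct", "blood_pct", "saliva_pct",
                  "buccal_pct", "of_40plus_pct")
}
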