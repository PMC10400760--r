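# internal helpers shared across modules

clamp01 <- function(x) pmin(pmax(x, 0), 1)  # argument order preserves dims

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if <- function(cond, msg) if (isTRUE(cond)) rlang::abort(msg)

# weighted first/second moments with weights normalized to sum 1
weighted_moments <- function(x, w) {
  v <- w / sum(w)
  mu <- sum(v * x)
  list(mean = mu, msd = sqrt(sum(v * (x - mu)^2)))
}

# derive a child seed from a global seed and a stage label, kept below 2^31
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  (as.integer(seed) * 1009L + as.integer(h %% 104729L)) %% 2147483399L
}

# check a beta matrix: numeric, rows = CpGs (named), cols = samples (named)
check_beta_matrix <- function(beta) {
  stop_if(!is.matrix(beta) || !is.numeric(beta),
          "`beta` must be a numeric matrix (CpGs x samples)")
  stop_if(is.null(rownames(beta)) || is.null(colnames(beta)),
          "`beta` must carry CpG rownames and sample colnames")
  stop_if(anyDuplicated(rownames(beta)) > 0, "duplicate CpG ids in `beta`")
  stop_if(anyDuplicated(colnames(beta)) > 0, "duplicate sample ids in `beta`")
  rng <- range(beta, na.rm = TRUE)
  stop_if(rng[1] < 0 || rng[2] > 1, "beta values must lie in [0, 1]")
  invisible(beta)
}

check_sample_sheet <- function(sheet) {
  stop_if(!is.data.frame(sheet), "`sheet` must be a data frame")
  stop_if(!all(c("sample_id", "age") %in% names(sheet)),
          "`sheet` needs at least `sample_id` and `age` columns")
  stop_if(anyDuplicated(sheet$sample_id) > 0, "duplicate sample ids in sheet")
  stop_if(any(sheet$age < 0), "ages must be non-negative")
  invisible(sheet)
}

align_sheet_to_beta <- function(beta, sheet) {
  stop_if(!all(colnames(beta) %in% sheet$sample_id),
          "every beta column needs a sample sheet row")
  sheet[match(colnames(beta), sheet$sample_id), , drop = FALSE]
}

# log(sum(exp(x))) guarded against -Inf-only input
log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
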