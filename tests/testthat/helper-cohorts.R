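# Randomized cohort and spec generators for property-style tests.
# Deaths are kept strictly positive in every cell so that RRs and pd are
# always defined.

random_cohort <- function(n_strata = NULL, n_levels = NULL) {
  n_strata <- n_strata %||% sample(1:4, 1)
  n_levels <- n_levels %||% sample(2:3, 1)
  strata <- paste0("s", seq_len(n_strata))
  levels <- c("ref", paste0("exp", seq_len(n_levels - 1)))
  counts <- expand.grid(stratum = strata, level = levels,
                        stringsAsFactors = FALSE)
  counts$died <- sample(1:200, nrow(counts), replace = TRUE)
  counts$survived <- sample(1:2000, nrow(counts), replace = TRUE)
  cohort(counts, reference = "ref")
}

random_population_spec <- function(n_strata = NULL, n_levels = NULL) {
  n_strata <- n_strata %||% sample(1:3, 1)
  n_levels <- n_levels %||% sample(2:3, 1)
  levels <- c("ref", paste0("exp", seq_len(n_levels - 1)))
  strata <- lapply(seq_len(n_strata), function(i) {
    pe <- stats::runif(n_levels, 0.05, 1)
    pe <- pe / sum(pe)
    list(id = paste0("s", i),
         N = sample(500:5000, 1),
         prevalence = stats::setNames(pe, levels),
         qx = stats::setNames(stats::runif(n_levels, 0.01, 0.6), levels))
  })
  population_spec(strata, reference = "ref")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
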