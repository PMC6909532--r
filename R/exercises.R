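#' Worked analyses: confounding, selection, and survey data
#'
#' Three end-to-end pipelines that exercise the whole package on the
#' bundled scenarios ([paf_fixtures()]) and return every intermediate
#' quantity with provenance:
#' \describe{
#'   \item{[run_exercise1()]}{observed confounding: crude vs stratum vs
#'     weighted-sum vs counterfactual PAF on the two-race hypothetical
#'     cohort.}
#'   \item{[run_exercise2()]}{endogenous selection: the true population PAF
#'     vs the PAF the health-selected sample yields, including the residual
#'     bias of the pd-based formula even after the risk ratios are
#'     corrected.}
#'   \item{[run_exercise3()]}{survey data with a two-level exposure (former
#'     and current smokers): unadjusted risk ratios, multi-level PAFs, the
#'     baseline discrete-time model, and — when users supply adjusted RRs or
#'     published PAF pairs — the assembly of model-based PAFs and the
#'     pd-vs-pe bias comparison.}
#' }
#'
#' @name exercises
NULL

exercise_report <- function(exercise, mode, values, results, inputs) {
  structure(list(exercise = exercise, mode = mode, values = values,
                 results = results, inputs = inputs),
            class = "exercise_report")
}

#' @export
print.exercise_report <- function(x, digits = 3, ...) {
  cat("== Exercise ", x$exercise, " (", x$mode, ") ==\n", sep = "")
  v <- unlist(x$values)
  tab <- data.frame(quantity = names(v),
                    value = round_half_up(v, digits))
  print(tab, row.names = FALSE, right = FALSE)
  invisible(x)
}

#' Serialize an exercise report to JSON
#' @param x an `exercise_report`.
#' @return JSON string with all reported values.
#' @export
exercise_report_json <- function(x) {
  stopifnot(inherits(x, "exercise_report"))
  jsonlite::toJSON(list(exercise = x$exercise, mode = x$mode,
                        values = x$values),
                   auto_unbox = TRUE, digits = NA)
}

#' @rdname exercises
#' @return an `exercise_report`; `$values` is a named list of every
#'   reported number, `$results` holds the underlying `paf_result` objects.
#' @examples
#' run_exercise1()
#' @export
run_exercise1 <- function() {
  coh <- paf_fixtures()$table1
  crude_pd <- cohort_paf(coh, "pd", stratified = FALSE)
  crude_pe <- cohort_paf(coh, "pe", stratified = FALSE)
  ws_pd <- cohort_paf(coh, "pd")
  ws_pe <- cohort_paf(coh, "pe")
  cf <- counterfactual_paf(coh)
  values <- list(
    crude_paf_pd = crude_pd$value,
    crude_paf_pe = crude_pe$value,
    stratum_paf = as.list(ws_pd$stratum_values),
    weights = as.list(ws_pd$weights),
    weighted_sum_paf_pd = ws_pd$value,
    weighted_sum_paf_pe = ws_pe$value,
    counterfactual_paf = cf$value,
    adjusted_rr_mantel_haenszel = unname(standardized_rr(coh)),
    adjusted_rr_death_weighted = unname(standardized_rr(coh, "death_weighted"))
  )
  exercise_report(1, "full_precision", values,
                  results = list(crude_pd = crude_pd, crude_pe = crude_pe,
                                 weighted_sum_pd = ws_pd,
                                 weighted_sum_pe = ws_pe,
                                 counterfactual = cf),
                  inputs = list(cohort = coh))
}

#' @rdname exercises
#' @param mode `"full_precision"` (default) or `"replication"`; replication
#'   mode reproduces hand arithmetic carried out on intermediates rounded to
#'   3 decimals.
#' @param overall_adjusted_rr single pooled adjusted RR used for the
#'   whole-sample pd-formula shortcut (default 2.8, the value the selection
#'   scenario attributes to a fully adjusted pooled model).
#' @export
run_exercise2 <- function(mode = c("full_precision", "replication"),
                          overall_adjusted_rr = 2.8) {
  mode <- match.arg(mode)
  fx <- paf_fixtures()
  pair <- simulate_pair(fx$table2_population, fx$table2_sample,
                        mode = "expected")
  population <- pair$population
  sample_cohort <- pair$sample

  pop_ws <- cohort_paf(population, "pe", mode = mode)
  pop_cf <- counterfactual_paf(population)
  sample_ws <- cohort_paf(sample_cohort, "pe", mode = mode)

  # population ("selection-adjusted") RRs applied to the biased sample
  pop_rrs <- do.call(rbind, lapply(summarize_cohort(population), function(s) {
    tab <- s$levels[s$levels$level != s$reference, , drop = FALSE]
    data.frame(stratum = s$stratum, level = tab$level, rr = tab$rr)
  }))
  adj_pd <- paf_from_adjusted_rrs(sample_cohort, pop_rrs, "pd", mode = mode)
  adj_pe <- paf_from_adjusted_rrs(sample_cohort, pop_rrs, "pe", mode = mode)

  # whole-sample shortcut: observed pooled pd with a single adjusted RR
  pooled <- summarize_stratum(aggregate(sample_cohort))
  pd_pooled <- sum(pooled$levels$pd[pooled$levels$level != pooled$reference])
  overall_pd <- paf_pd(pd_pooled, overall_adjusted_rr)

  maybe_round <- function(v) if (mode == "replication") round_half_up(v, 3) else v
  # the truth is the full-precision population PAF whatever the display mode
  truth <- cohort_paf(population, "pe")$value
  values <- list(
    population_stratum_paf = as.list(pop_ws$stratum_values),
    population_weighted_sum_paf = pop_ws$value,
    population_counterfactual_paf = pop_cf$value,
    sample_weighted_sum_paf = sample_ws$value,
    adjusted_rr_paf_pd_stratum = as.list(adj_pd$stratum_values),
    adjusted_rr_paf_pd = adj_pd$value,
    adjusted_rr_paf_pe_stratum = as.list(adj_pe$stratum_values),
    adjusted_rr_paf_pe = adj_pe$value,
    overall_adjusted_rr_paf_pd = overall_pd,
    bias_paf_pd_overall = proportionate_bias(maybe_round(overall_pd),
                                             maybe_round(truth)),
    bias_paf_pe_weighted = proportionate_bias(maybe_round(adj_pe$value),
                                              maybe_round(truth)),
    bias_sample_vs_population = proportionate_bias(maybe_round(sample_ws$value),
                                                   maybe_round(truth))
  )
  exercise_report(2, mode, values,
                  results = list(population_ws = pop_ws,
                                 population_cf = pop_cf,
                                 sample_ws = sample_ws,
                                 adjusted_pd = adj_pd, adjusted_pe = adj_pe),
                  inputs = list(population = population,
                                sample = sample_cohort))
}

#' @rdname exercises
#' @param rr_source `"unadjusted"` (risk ratios computed from the counts) or
#'   `"user_supplied"` (adjusted RRs and/or a published PAF pair provided by
#'   the caller, e.g. from confounder- or bias-adjusted survival models).
#' @param rrs (user_supplied) data frame `stratum`, `level`, `rr` of
#'   adjusted RRs for every age stratum and smoking level.
#' @param paf_pair (user_supplied) named vector `c(pd = ..., pe = ...)` of
#'   already-assembled model PAFs; used to compute the pd-vs-pe
#'   proportionate bias.
#' @export
run_exercise3 <- function(rr_source = c("unadjusted", "user_supplied"),
                          rrs = NULL, paf_pair = NULL) {
  rr_source <- match.arg(rr_source)
  coh <- paf_fixtures()$table3
  totals <- summarize_stratum(aggregate(coh))
  nonref <- totals$levels[totals$levels$level != totals$reference, ,
                          drop = FALSE]
  paf_pd_total <- paf_pd_multilevel(nonref$pd, nonref$rr)
  paf_pe_total <- paf_pe_multilevel(nonref$pe, nonref$rr)

  # baseline discrete-time model: one period per age stratum; standardized
  # risk ratios recover the unadjusted total RRs
  pp <- cohort_to_person_periods(coh)
  baseline <- fit_cloglog(died ~ exposure, pp, weights = pp$weight)
  baseline_rr <- risk_ratios(baseline, pp, "exposure", weights = pp$weight)

  values <- list(
    unadjusted_rr = stats::setNames(as.list(nonref$rr), nonref$level),
    pe = stats::setNames(as.list(nonref$pe), nonref$level),
    pd = stats::setNames(as.list(nonref$pd), nonref$level),
    two_level_paf_pd = paf_pd_total,
    two_level_paf_pe = paf_pe_total,
    baseline_model_rr = as.list(baseline_rr)
  )
  results <- list(totals = totals, baseline_fit = baseline)

  if (rr_source == "user_supplied") {
    if (is.null(rrs) && is.null(paf_pair)) {
      stop_data("rr_source = 'user_supplied' needs rrs and/or paf_pair")
    }
    if (!is.null(rrs)) {
      adj_pd <- rr_table_to_paf(coh, rrs, "pd")
      adj_pe <- rr_table_to_paf(coh, rrs, "pe")
      values$adjusted_paf_pd <- adj_pd$value
      values$adjusted_paf_pe <- adj_pe$value
      values$bias_pd_vs_pe <- proportionate_bias(adj_pd$value, adj_pe$value)
      results$adjusted_pd <- adj_pd
      results$adjusted_pe <- adj_pe
    }
    if (!is.null(paf_pair)) {
      if (!all(c("pd", "pe") %in% names(paf_pair))) {
        stop_data("paf_pair must be named c(pd = ..., pe = ...)")
      }
      values$supplied_paf_pd <- unname(paf_pair["pd"])
      values$supplied_paf_pe <- unname(paf_pair["pe"])
      values$supplied_bias_pd_vs_pe <-
        proportionate_bias(paf_pair[["pd"]], paf_pair[["pe"]])
    }
  }
  exercise_report(3, "full_precision", values, results,
                  inputs = list(cohort = coh))
}
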