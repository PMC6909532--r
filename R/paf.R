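#' Population attributable fraction from the prevalence of exposure among
#' the deceased (Miettinen-type formula)
#'
#' PAF_pd = pd (RR - 1) / RR, where pd is the proportion of the deceased who
#' were exposed and RR the mortality risk ratio of exposed vs unexposed.
#' With a confounder-adjusted RR this formula is consistent under confounding,
#' but it inherits any bias in pd itself — the property that makes it
#' vulnerable to selection (collider) bias.
#'
#' @param pd proportion of deceased who were exposed, in \[0, 1\].
#' @param rr mortality risk ratio (exposed vs reference), > 0.
#' @return the attributable fraction; negative when RR < 1 (protective
#'   exposure), in which case a warning is raised.
#' @examples
#' paf_pd(0.5, 1.86)    # black stratum of the two-race hypothetical cohort
#' paf_pd(0.409, 2.32)  # crude (confounded) estimate from the pooled counts
#' @export
paf_pd <- function(pd, rr) {
  check_prop(pd, "pd")
  check_rr(rr)
  warn_if_protective(rr)
  pd * (rr - 1) / rr
}

#' Population attributable fraction from the prevalence of exposure in the
#' whole cohort (Levin-type formula)
#'
#' PAF_pe = pe (RR - 1) / (1 + pe (RR - 1)), where pe is the proportion of
#' the entire cohort that was exposed.  Used stratum-by-stratum with adjusted
#' RRs and death-share weights, it matches the pd-based formula under
#' confounding; under endogenous selection it is the less biased of the two
#' because pe, unlike pd, is not distorted by under-counted deaths.
#'
#' @param pe proportion of the cohort exposed, in \[0, 1\].
#' @param rr mortality risk ratio (exposed vs reference), > 0.
#' @return the attributable fraction.
#' @examples
#' paf_pe(0.35, 1.86)
#' @export
paf_pe <- function(pe, rr) {
  check_prop(pe, "pe")
  check_rr(rr)
  warn_if_protective(rr)
  excess <- pe * (rr - 1)
  if (any(1 + excess <= 0)) {
    stop_data("paf_pe: denominator 1 + pe*(RR-1) must be positive")
  }
  excess / (1 + excess)
}

#' Multi-level-exposure PAF formulas
#'
#' Extensions of the two-level formulas to an exposure with several
#' non-reference levels (e.g. former and current smokers vs never smokers).
#' The pd form sums the per-level Miettinen terms; the pe form pools the
#' per-level excesses into a single Levin ratio:
#' \deqn{PAF_{pd} = \sum_k pd_k (RR_k - 1)/RR_k}
#' \deqn{PAF_{pe} = \sum_k pe_k (RR_k - 1) \big/ (1 + \sum_k pe_k (RR_k - 1))}
#' With a single non-reference level both reduce exactly to [paf_pd()] and
#' [paf_pe()].
#'
#' @param pd,pe per-level proportions (reference level excluded); `pd` must
#'   sum to at most 1.
#' @param rr per-level risk ratios vs the reference, all > 0.
#' @return the attributable fraction over all exposure levels jointly.
#' @examples
#' paf_pd_multilevel(c(0.352, 0.338), c(1.489, 1.524))
#' paf_pe_multilevel(c(0.308, 0.289), c(1.489, 1.524))
#' @export
paf_pd_multilevel <- function(pd, rr) {
  if (length(pd) != length(rr)) stop_data("pd and rr must have equal length")
  check_prop(pd, "pd")
  check_rr(rr)
  if (sum(pd) > 1 + 1e-12) stop_data("per-level pd values sum to more than 1")
  warn_if_protective(rr)
  sum(pd * (rr - 1) / rr)
}

#' @rdname paf_pd_multilevel
#' @export
paf_pe_multilevel <- function(pe, rr) {
  if (length(pe) != length(rr)) stop_data("pe and rr must have equal length")
  check_prop(pe, "pe")
  check_rr(rr)
  if (sum(pe) > 1 + 1e-12) stop_data("per-level pe values sum to more than 1")
  warn_if_protective(rr)
  excess <- sum(pe * (rr - 1))
  if (1 + excess <= 0) stop_data("paf_pe: denominator 1 + sum(pe*(RR-1)) must be positive")
  excess / (1 + excess)
}

check_prop <- function(p, what) {
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop_data(what, " must lie in [0, 1]")
  }
}
check_rr <- function(rr) {
  if (anyNA(rr) || any(rr <= 0)) stop_data("RR must be positive")
}
warn_if_protective <- function(rr) {
  if (any(rr < 1)) {
    warning("RR < 1: protective exposure yields a negative attributable fraction",
            call. = FALSE)
  }
}

#' PAF result container
#'
#' Carries a PAF value together with its provenance: which formula produced
#' it (`pd` or `pe`), its scope (`crude`, `stratum`, `weighted_sum`, or
#' `counterfactual`), any per-stratum values and standardization weights, and
#' whether full-precision or replication (rounded-intermediate) arithmetic
#' was used.
#'
#' @param value the attributable fraction.
#' @param formula `"pd"`, `"pe"`, or `"counterfactual"`.
#' @param scope one of `"crude"`, `"stratum"`, `"weighted_sum"`,
#'   `"counterfactual"`.
#' @param stratum_values optional named per-stratum PAFs.
#' @param weights optional named standardization weights.
#' @param mode `"full_precision"` or `"replication"`.
#' @param details optional list of extra provenance (e.g. counterfactual
#'   death counts).
#' @return an object of class `paf_result`.
#' @export
paf_result <- function(value, formula, scope, stratum_values = NULL,
                       weights = NULL, mode = "full_precision",
                       details = NULL) {
  structure(
    list(value = value, formula = formula, scope = scope,
         stratum_values = stratum_values, weights = weights,
         mode = mode, details = details),
    class = "paf_result"
  )
}

#' @export
print.paf_result <- function(x, digits = 3, ...) {
  cat("PAF (", x$formula, ", ", x$scope,
      if (x$mode != "full_precision") paste0(", ", x$mode), "): ",
      round_half_up(x$value, digits), "\n", sep = "")
  if (!is.null(x$stratum_values)) {
    cat("  per stratum:",
        paste(names(x$stratum_values),
              round_half_up(x$stratum_values, digits), sep = " = ",
              collapse = ", "), "\n")
  }
  if (!is.null(x$weights)) {
    cat("  weights:",
        paste(names(x$weights), round_half_up(x$weights, digits),
              sep = " = ", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
as.double.paf_result <- function(x, ...) x$value

#' Serialize a PAF result to JSON
#' @param x a `paf_result`.
#' @return a JSON string with full provenance fields.
#' @export
paf_result_json <- function(x) {
  stopifnot(inherits(x, "paf_result"))
  out <- unclass(x)
  # keep stratum names: named atomic vectors serialize as JSON objects
  for (f in c("stratum_values", "weights")) {
    if (!is.null(out[[f]])) out[[f]] <- as.list(out[[f]])
  }
  jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, null = "null")
}

#' Weighted-sum standardization of stratum-specific PAFs
#'
#' Combines confounder-stratum PAFs into one standardized PAF using each
#' stratum's share of deaths: PAF = sum_i W_i PAF_i.  In `replication` mode
#' the stratum PAFs and weights are first rounded half-up to 3 decimals,
#' reproducing hand calculations carried out on rounded intermediates;
#' the default keeps full precision.
#'
#' @param stratum_pafs named numeric vector of per-stratum PAFs.
#' @param weights named weights (e.g. from [death_share_weights()]); must
#'   cover the same strata and sum to 1.
#' @param formula label recorded in the result (`"pd"` or `"pe"`).
#' @param mode `"full_precision"` (default) or `"replication"`.
#' @return a `paf_result` with scope `"weighted_sum"`.
#' @examples
#' weighted_sum_paf(c(black = 0.231, white = 0.219),
#'                  c(black = 0.273, white = 0.727))
#' @export
weighted_sum_paf <- function(stratum_pafs, weights, formula = "pd",
                             mode = c("full_precision", "replication")) {
  mode <- match.arg(mode)
  if (is.null(names(stratum_pafs)) || is.null(names(weights))) {
    stop_data("stratum_pafs and weights must be named by stratum")
  }
  if (!setequal(names(stratum_pafs), names(weights))) {
    stop_data("stratum_pafs and weights cover different strata")
  }
  weights <- weights[names(stratum_pafs)]
  if (abs(sum(weights) - 1) > 1e-8) stop_data("weights must sum to 1")
  p <- stratum_pafs
  w <- weights
  if (mode == "replication") {
    p <- round_half_up(p, 3)
    w <- round_half_up(w, 3)
  }
  paf_result(sum(w * p), formula = formula, scope = "weighted_sum",
             stratum_values = stratum_pafs, weights = weights, mode = mode)
}

#' PAF of one stratum (or a pooled cohort) from its counts
#'
#' Convenience wrapper: computes the multi-level PAF of a stratum summary
#' using either formula, over all non-reference levels.
#'
#' @param summary a `stratum_summary` from [summarize_stratum()].
#' @param formula `"pd"` or `"pe"`.
#' @return a `paf_result` with scope `"stratum"`.
#' @export
stratum_paf <- function(summary, formula = c("pd", "pe")) {
  formula <- match.arg(formula)
  stopifnot(inherits(summary, "stratum_summary"))
  tab <- summary$levels
  nonref <- tab[tab$level != summary$reference, , drop = FALSE]
  value <- if (formula == "pd") {
    paf_pd_multilevel(nonref$pd, nonref$rr)
  } else {
    paf_pe_multilevel(nonref$pe, nonref$rr)
  }
  paf_result(value, formula = formula, scope = "stratum")
}

#' Crude and standardized PAF of a stratified cohort
#'
#' With `stratified = FALSE` the cohort is pooled and the crude PAF computed
#' — the estimate a confounded analysis reports.  With `stratified = TRUE`
#' (default) per-stratum PAFs are combined by the weighted-sum approach with
#' death-share weights, which recovers the true PAF under observed
#' confounding.
#'
#' @param x a `paf_cohort`.
#' @param formula `"pd"` or `"pe"`.
#' @param stratified pool (`FALSE`) or standardize over strata (`TRUE`).
#' @param mode passed to [weighted_sum_paf()].
#' @return a `paf_result`.
#' @export
cohort_paf <- function(x, formula = c("pd", "pe"), stratified = TRUE,
                       mode = "full_precision") {
  formula <- match.arg(formula)
  stopifnot(inherits(x, "paf_cohort"))
  if (!stratified) {
    pooled <- summarize_stratum(aggregate(x))
    res <- stratum_paf(pooled, formula)
    res$scope <- "crude"
    return(res)
  }
  pafs <- vapply(summarize_cohort(x),
                 function(s) stratum_paf(s, formula)$value, numeric(1))
  weighted_sum_paf(pafs, death_share_weights(x), formula = formula, mode = mode)
}

#' Counterfactual (true) PAF of a closed cohort
#'
#' The ground truth of the stratified scenario: apply each stratum's
#' reference-level death probability to the entire stratum to obtain the
#' deaths expected had no one been exposed, then form
#' (observed deaths - counterfactual deaths) / observed deaths.
#' Algebraically this equals the weighted sum of per-stratum pd-based PAFs
#' with death-share weights.
#'
#' @param x a `paf_cohort`.
#' @return a `paf_result` with scope `"counterfactual"`; `details$table`
#'   holds per-stratum observed and counterfactual death/survivor counts.
#' @examples
#' counts <- data.frame(
#'   stratum  = rep(c("black", "white"), each = 2),
#'   level    = rep(c("nonsmoker", "smoker"), 2),
#'   survived = c(500, 200, 2700, 500),
#'   died     = c(150, 150, 500, 300)
#' )
#' counterfactual_paf(cohort(counts, reference = "nonsmoker"))
#' @export
counterfactual_paf <- function(x) {
  stopifnot(inherits(x, "paf_cohort"))
  summaries <- summarize_cohort(x)
  tab <- do.call(rbind, lapply(summaries, function(s) {
    qref <- s$levels$qx[s$levels$level == s$reference]
    data.frame(
      stratum = s$stratum,
      n = s$total,
      observed_died = s$deaths,
      counterfactual_died = s$total * qref,
      counterfactual_survived = s$total * (1 - qref),
      row.names = NULL
    )
  }))
  D <- sum(tab$observed_died)
  if (D <= 0) stop_data("cohort has zero total deaths")
  D_cf <- sum(tab$counterfactual_died)
  paf_result((D - D_cf) / D, formula = "counterfactual",
             scope = "counterfactual",
             details = list(table = tab, observed_deaths = D,
                            counterfactual_deaths = D_cf))
}

#' Stratified (confounder-adjusted) risk ratio
#'
#' Standardizes per-stratum risk ratios of one exposure level against the
#' reference into a single adjusted RR.  `mantel_haenszel` (default) is the
#' field-standard stratified risk ratio,
#' \eqn{\sum_i a_i n_{0i}/n_i \big/ \sum_i c_i n_{1i}/n_i}
#' with a = exposed deaths, c = reference deaths, n1/n0 the exposed and
#' reference totals and n their sum within the stratum; `death_weighted`
#' averages stratum RRs with death-share weights, \eqn{\sum_i W_i RR_i}.
#'
#' @param x a `paf_cohort`.
#' @param method `"mantel_haenszel"` or `"death_weighted"`.
#' @param level exposure level(s) to contrast against the reference; default
#'   all non-reference levels.
#' @return named numeric vector of adjusted RRs, one per requested level.
#' @export
standardized_rr <- function(x, method = c("mantel_haenszel", "death_weighted"),
                            level = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(x, "paf_cohort"))
  levels <- level %||% setdiff(x$levels, x$reference)
  if (any(!levels %in% x$levels) || x$reference %in% levels) {
    stop_data("level must name non-reference exposure levels of the cohort")
  }
  cts <- x$counts
  ref <- x$reference
  out <- vapply(levels, function(lv) {
    ex <- cts[cts$level == lv, , drop = FALSE]
    rf <- cts[cts$level == ref, , drop = FALSE]
    rf <- rf[match(ex$stratum, rf$stratum), , drop = FALSE]
    n1 <- ex$survived + ex$died
    n0 <- rf$survived + rf$died
    n <- n1 + n0
    if (method == "mantel_haenszel") {
      num <- sum(ex$died * n0 / n)
      den <- sum(rf$died * n1 / n)
      if (den <= 0) stop_data("Mantel-Haenszel denominator is zero")
      num / den
    } else {
      w <- death_share_weights(x)
      rrs <- vapply(summarize_cohort(x), function(s) {
        s$levels$rr[s$levels$level == lv]
      }, numeric(1))
      sum(w * rrs[names(w)])
    }
  }, numeric(1))
  stats::setNames(out, levels)
}

#' Proportionate bias of an estimate against a reference value
#'
#' (estimate - truth) / truth, the signed relative error used to compare a
#' biased PAF with the true (population or counterfactual) PAF.
#'
#' @param estimate the biased or candidate value.
#' @param truth the reference value; must be non-zero.
#' @return signed proportion.
#' @examples
#' proportionate_bias(0.263, 0.301)  # about -12.6%
#' @export
proportionate_bias <- function(estimate, truth) {
  if (any(truth == 0)) stop_data("truth must be non-zero")
  (estimate - truth) / truth
}

#' PAF from externally supplied (adjusted) risk ratios
#'
#' Evaluates the chosen PAF formula stratum by stratum using adjusted RRs
#' supplied by the user (e.g. from confounder- or bias-adjusted survival
#' models) together with the pe or pd observed in the — possibly
#' selection-biased — cohort, then standardizes with death-share weights.
#' This is the operation that exposes the pd-formula's residual selection
#' bias: adjusted RRs repair the risk ratios but not a distorted pd or
#' distorted weights.
#'
#' @param x a `paf_cohort` (source of the observed pe/pd and, by default,
#'   the weights).
#' @param rrs data frame with columns `stratum`, `level`, `rr` giving an
#'   adjusted RR for every stratum x non-reference level.
#' @param formula `"pd"` or `"pe"`.
#' @param weights optional named weights; default [death_share_weights()] of
#'   `x`.
#' @param mode passed to [weighted_sum_paf()].
#' @return a `paf_result` with per-stratum values and weights recorded.
#' @export
paf_from_adjusted_rrs <- function(x, rrs, formula = c("pd", "pe"),
                                  weights = NULL,
                                  mode = "full_precision") {
  formula <- match.arg(formula)
  stopifnot(inherits(x, "paf_cohort"))
  required <- c("stratum", "level", "rr")
  if (!all(required %in% names(rrs))) {
    stop_data("rrs must have columns stratum, level, rr")
  }
  if (any(rrs$rr <= 0)) stop_data("adjusted RRs must be positive")
  nonref <- setdiff(x$levels, x$reference)
  summaries <- summarize_cohort(x)
  pafs <- vapply(summaries, function(s) {
    tab <- s$levels[s$levels$level != s$reference, , drop = FALSE]
    rr_k <- vapply(tab$level, function(lv) {
      hit <- rrs$rr[rrs$stratum == s$stratum & rrs$level == lv]
      if (length(hit) != 1) {
        stop_data("missing or duplicated adjusted RR for stratum '",
                  s$stratum, "', level '", lv, "'")
      }
      hit
    }, numeric(1))
    if (formula == "pd") paf_pd_multilevel(tab$pd, rr_k)
    else paf_pe_multilevel(tab$pe, rr_k)
  }, numeric(1))
  weights <- weights %||% death_share_weights(x)
  weighted_sum_paf(pafs, weights, formula = formula, mode = mode)
}

#' Assemble PAFs and formula-comparison bias from fitted or published RRs
#'
#' Bridge from survival-model output to the PAF machinery: given a table of
#' adjusted RRs (for example exponentiated discrete-time model coefficients,
#' or published model RRs), delegates to [paf_from_adjusted_rrs()].  When
#' both formulas' PAFs are available, [proportionate_bias()] of the pd-based
#' against the pe-based value quantifies how much the pd route understates
#' the attributable fraction under selection bias.
#'
#' @inheritParams paf_from_adjusted_rrs
#' @return a `paf_result`.
#' @export
rr_table_to_paf <- function(x, rrs, formula = c("pd", "pe"), weights = NULL,
                            mode = "full_precision") {
  paf_from_adjusted_rrs(x, rrs, formula = formula, weights = weights,
                        mode = mode)
}
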