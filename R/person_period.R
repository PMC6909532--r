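#' Simulate discrete-time survival data in person-period form
#'
#' Generates subjects followed over discrete periods (half-open age
#' intervals) until death or end of follow-up, with death probability in
#' each period given by the complementary log-log model
#' \deqn{q = 1 - \exp(-\exp(\eta)), \quad
#'       \eta = \alpha + \gamma_t + \beta x + b_g}
#' where \eqn{\gamma_t} is the period effect, x a binary exposure, and
#' \eqn{b_g \sim N(0, \sigma^2)} an optional group-level (entry-cohort)
#' random intercept.
#'
#' With `entry = "staggered"` groups enter follow-up at increasingly late
#' periods and only subjects who survive the pre-entry periods are observed
#' — the endogenous-selection device of aging survey panels: late-entering
#' observed subjects are survivors, so high-mortality groups (and, when the
#' exposure raises mortality, exposed subjects especially) are
#' under-represented, attenuating the marginal exposure effect while the
#' group-conditional effect is unchanged.
#'
#' @param n_subjects number of subjects to draw.
#' @param n_periods number of follow-up periods.
#' @param intercept baseline log-hazard intercept \eqn{\alpha}.
#' @param exposure_coef log hazard ratio \eqn{\beta} of the exposure.
#' @param exposure_prevalence probability a subject is exposed.
#' @param period_effects numeric vector of per-period additive effects
#'   \eqn{\gamma_t} (recycled to `n_periods`; default 0).
#' @param re_sd standard deviation \eqn{\sigma} of the group random
#'   intercept (0 disables it).
#' @param n_groups number of groups; subjects are assigned uniformly.
#' @param entry `"baseline"` (everyone observed from period 1) or
#'   `"staggered"` (group g enters at period 1 + (g-1) mod
#'   ceil(n_periods/2), conditional on surviving earlier periods).
#' @param seed integer RNG seed.
#' @return data frame with one row per observed subject-period: columns
#'   `subject`, `group`, `entry_period`, `period`, `exposure`, `died`.  A
#'   subject has no rows after its death row.
#' @examples
#' pp <- simulate_person_periods(500, 3, intercept = -2,
#'                               exposure_coef = log(2), seed = 1)
#' head(pp)
#' @export
simulate_person_periods <- function(n_subjects, n_periods, intercept,
                                    exposure_coef = 0,
                                    exposure_prevalence = 0.5,
                                    period_effects = 0,
                                    re_sd = 0, n_groups = 1,
                                    entry = c("baseline", "staggered"),
                                    seed = NULL) {
  entry <- match.arg(entry)
  stopifnot(n_subjects >= 1, n_periods >= 1, n_groups >= 1)
  period_effects <- rep_len(period_effects, n_periods)
  if (!all(is.finite(c(intercept, exposure_coef, period_effects, re_sd)))) {
    stop_data("model coefficients must be finite")
  }
  sim <- function() {
    exposure <- stats::rbinom(n_subjects, 1, exposure_prevalence)
    group <- ((seq_len(n_subjects) - 1) %% n_groups) + 1
    b <- if (re_sd > 0) stats::rnorm(n_groups, 0, re_sd) else rep(0, n_groups)
    entry_period <- if (entry == "staggered") {
      1 + (group - 1) %% max(1, ceiling(n_periods / 2))
    } else {
      rep(1L, n_subjects)
    }
    eta <- outer(intercept + exposure_coef * exposure + b[group],
                 period_effects, `+`)
    if (any(!is.finite(eta))) stop_data("non-finite linear predictor")
    q <- -expm1(-exp(eta))
    death <- matrix(stats::rbinom(length(q), 1, q), nrow = n_subjects)
    # full latent history from period 1; death period (Inf if survivor)
    first_death <- apply(death == 1, 1, function(z) {
      d <- which(z)
      if (length(d)) d[1] else Inf
    })
    observed <- first_death >= entry_period  # died pre-entry: never observed
    e <- entry_period[observed]
    last <- pmin(first_death[observed], n_periods)
    len <- last - e + 1
    idx <- rep.int(which(observed), len)
    period <- sequence(len, from = e)
    out <- data.frame(
      subject = idx,
      group = group[idx],
      entry_period = entry_period[idx],
      period = period,
      exposure = exposure[idx],
      died = as.integer(period == first_death[idx])
    )
    rownames(out) <- NULL
    out
  }
  if (!is.null(seed)) with_local_seed(seed, sim()) else sim()
}

#' Expand a closed-cohort count table into aggregated person-period rows
#'
#' Turns each stratum x exposure-level cell of a `paf_cohort` into two
#' weighted person-period rows (died / survived) suitable for
#' [fit_cloglog()] with frequency weights: each stratum is treated as one
#' period (age interval) of follow-up.
#'
#' @param x a `paf_cohort`; strata are interpreted as age periods.
#' @return data frame with columns `period` (stratum id), `exposure`
#'   (level), `died` (0/1), `weight` (person count).
#' @export
cohort_to_person_periods <- function(x) {
  stopifnot(inherits(x, "paf_cohort"))
  cts <- x$counts
  out <- rbind(
    data.frame(period = cts$stratum, exposure = cts$level, died = 1,
               weight = cts$died),
    data.frame(period = cts$stratum, exposure = cts$level, died = 0,
               weight = cts$survived)
  )
  out <- out[out$weight > 0, , drop = FALSE]
  out$exposure <- factor(out$exposure, levels = x$levels)
  out$period <- factor(out$period, levels = strata_ids(x))
  rownames(out) <- NULL
  out
}
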