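#' Bundled hypothetical and survey-based count scenarios
#'
#' Ready-made inputs for the three worked analyses this package ships:
#' \describe{
#'   \item{`table1`}{hypothetical two-race cohort (1000 black, 4000 white
#'     respondents) in which both smoking prevalence and mortality are
#'     higher among black respondents, confounding the crude smoking-
#'     mortality association.}
#'   \item{`table2_population`}{a `population_spec` for the matching true
#'     population, identical except that smokers in both strata die with
#'     probability 0.50; the gap between it and `table1` is the imprint of
#'     health-selective sampling.  Never-smoker death probabilities are the
#'     exact sample fractions (150/650 and 500/3200).}
#'   \item{`table2_sample`}{the `selection_spec` (direct-risk mode) that
#'     turns the population of `table2_population` into the observed
#'     `table1` sample.}
#'   \item{`table3`}{age-stratified never/former/current smoker mortality
#'     counts for US black and white adults aged 50-84 (survey-linked
#'     mortality follow-up), four age strata by three exposure levels.}
#' }
#'
#' @return named list with elements `table1` (`paf_cohort`),
#'   `table2_population` (`population_spec`), `table2_sample`
#'   (`selection_spec`), `table3` (`paf_cohort`).
#' @examples
#' fx <- paf_fixtures()
#' summarize_stratum(aggregate(fx$table1))
#' @export
paf_fixtures <- function() {
  extdata <- function(f) system.file("extdata", f, package = "pafbias",
                                     mustWork = TRUE)
  table1 <- read_cohort_csv(extdata("table1.csv"),
                            label = "hypothetical sample")
  table3 <- read_cohort_csv(extdata("table3.csv"),
                            label = "age-specific smoking mortality")
  table2_population <- population_spec(
    strata = list(
      list(id = "black", N = 1000,
           prevalence = c(nonsmoker = 0.65, smoker = 0.35),
           qx = c(nonsmoker = 150 / 650, smoker = 0.5)),
      list(id = "white", N = 4000,
           prevalence = c(nonsmoker = 0.80, smoker = 0.20),
           qx = c(nonsmoker = 500 / 3200, smoker = 0.5))
    ),
    reference = "nonsmoker",
    label = "hypothetical population"
  )
  table2_sample <- selection_spec(
    "direct_risk",
    qx = data.frame(stratum = c("black", "white"),
                    level = "smoker",
                    qx = c(150 / 350, 300 / 800))
  )
  list(table1 = table1,
       table2_population = table2_population,
       table2_sample = table2_sample,
       table3 = table3)
}
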