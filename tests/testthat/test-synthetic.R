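fx <- paf_fixtures()

table1_spec <- population_spec(
  strata = list(
    list(id = "black", N = 1000,
         prevalence = c(nonsmoker = 0.65, smoker = 0.35),
         qx = c(nonsmoker = 150 / 650, smoker = 150 / 350)),
    list(id = "white", N = 4000,
         prevalence = c(nonsmoker = 0.80, smoker = 0.20),
         qx = c(nonsmoker = 500 / 3200, smoker = 300 / 800))
  ),
  reference = "nonsmoker"
)

test_that("expected counts rebuild the hypothetical sample table exactly", {
  coh <- expected_counts(table1_spec)
  expect_equal(coh$counts[c("stratum", "level", "survived", "died")],
               fx$table1$counts[c("stratum", "level", "survived", "died")])
})

test_that("expected counts of the population scenario give the published totals", {
  coh <- expected_counts(fx$table2_population)
  cts <- coh$counts
  expect_equal(cts$died[cts$stratum == "black" & cts$level == "smoker"], 175)
  expect_equal(cts$died[cts$stratum == "white" & cts$level == "smoker"], 400)
  expect_equal(sum(cts$died), 1225)
  sums <- summarize_cohort(coh)
  expect_equal(round_half_up(sums$black$qx_total, 3), 0.325)
  expect_equal(round_half_up(sums$white$qx_total, 3), 0.225)
})

test_that("expected counts conserve N and vanish when mortality is zero", {
  set.seed(11)
  for (i in 1:20) {
    spec <- random_population_spec()
    coh <- expected_counts(spec)
    for (s in spec$strata) {
      rows <- coh$counts[coh$counts$stratum == s$id, ]
      n_cells <- rows$survived + rows$died
      expect_equal(n_cells, unname(s$N * s$prevalence[rows$level]),
                   tolerance = 1e-12)
    }
  }
  immortal <- random_population_spec()
  immortal$strata <- lapply(immortal$strata, function(s) {
    s$qx[] <- 0
    s
  })
  expect_true(all(expected_counts(immortal)$counts$died == 0))
})

test_that("fixtures carry the published marginal quantities", {
  pooled <- summarize_stratum(aggregate(fx$table1))
  expect_equal(pooled$levels$pe[pooled$levels$level == "smoker"], 0.23)
  t3 <- summarize_stratum(aggregate(fx$table3))
  expect_equal(round_half_up(t3$levels$qx[t3$levels$level == "never"], 3), 0.106)
})

test_that("the YAML population spec round-trips to the in-code fixture", {
  path <- system.file("extdata", "table2_population.yaml", package = "pafbias")
  spec <- read_population_spec(path)
  from_yaml <- expected_counts(spec)$counts
  from_code <- expected_counts(fx$table2_population)$counts
  expect_equal(from_yaml$died, from_code$died, tolerance = 1e-9)
  expect_equal(from_yaml$survived, from_code$survived, tolerance = 1e-9)
})

test_that("no selection means the sample is the population", {
  pair <- simulate_pair(fx$table2_population, selection_spec("none"))
  expect_equal(pair$sample$counts[c("survived", "died")],
               pair$population$counts[c("survived", "died")])

  stoch <- simulate_pair(fx$table2_population, selection_spec("none"),
                         mode = "stochastic", n = 5000, seed = 3)
  expect_equal(stoch$sample$counts, stoch$population$counts)
})

test_that("direct-risk selection reproduces the sample-vs-population device", {
  pair <- simulate_pair(fx$table2_population, fx$table2_sample,
                        mode = "expected")
  # sample == observed hypothetical table; population keeps its own risks
  expect_equal(pair$sample$counts[c("survived", "died")],
               fx$table1$counts[c("survived", "died")])
  expect_equal(round_half_up(cohort_paf(pair$sample, "pe")$value, 3), 0.222)
  expect_equal(round_half_up(cohort_paf(pair$population, "pe")$value, 3), 0.301)
})

test_that("identical seeds reproduce identical stochastic pairs", {
  a <- simulate_pair(fx$table2_population, fx$table2_sample,
                     mode = "stochastic", n = 2000, seed = 99)
  b <- simulate_pair(fx$table2_population, fx$table2_sample,
                     mode = "stochastic", n = 2000, seed = 99)
  expect_identical(a$population$counts, b$population$counts)
  expect_identical(a$sample$counts, b$sample$counts)
})

test_that("stochastic cell counts converge to the expected counts", {
  n <- 50000
  scale <- n / 5000  # spec population is 5000 strong
  pair <- simulate_pair(fx$table2_population, selection_spec("none"),
                        mode = "stochastic", n = n, seed = 12)
  expected <- expected_counts(fx$table2_population)$counts
  got <- pair$population$counts
  for (r in seq_len(nrow(expected))) {
    cell_n <- (expected$survived[r] + expected$died[r]) * scale
    p <- expected$died[r] / (expected$survived[r] + expected$died[r])
    se_died <- sqrt(cell_n * p * (1 - p) + cell_n * p^2) # cell size varies too
    expect_lt(abs(got$died[r] - expected$died[r] * scale), 3 * se_died + 1)
  }
})

test_that("latent-health selection depresses every stratum's sample RR (expected mode)", {
  sel <- selection_spec("latent_health", a0 = 0, a1 = 0.5, a1_exposed = 1.5,
                        b1 = -1)
  pair <- simulate_pair(fx$table2_population, sel, mode = "expected")
  for (id in strata_ids(pair$population)) {
    rr_pop <- summarize_stratum(pair$population, id)$levels$rr[2]
    rr_sam <- summarize_stratum(pair$sample, id)$levels$rr[2]
    expect_lt(rr_sam, rr_pop)
  }
})

test_that("latent-health expectations agree with direct numerical integration", {
  sel <- selection_spec("latent_health", a0 = -0.3, a1 = 0.7, a1_exposed = 1.4,
                        a2 = 0.2, b1 = -0.8)
  pair <- simulate_pair(fx$table2_population, sel, mode = "expected")
  cts <- pair$sample$counts
  # oracle: adaptive quadrature over the latent health distribution
  spec <- fx$table2_population
  for (s in spec$strata) {
    for (lv in spec$levels) {
      exposed <- as.numeric(lv != spec$reference)
      slope <- if (exposed) sel$a1_exposed else sel$a1
      inc <- function(u) stats::plogis(sel$a0 + slope * u + sel$a2 * exposed)
      die <- function(u) stats::plogis(stats::qlogis(s$qx[[lv]]) + sel$b1 * u)
      n_cell <- s$N * s$prevalence[[lv]]
      n_samp <- n_cell * stats::integrate(function(u) inc(u) * stats::dnorm(u),
                                          -Inf, Inf, rel.tol = 1e-10)$value
      d_samp <- n_cell * stats::integrate(function(u) inc(u) * die(u) * stats::dnorm(u),
                                          -Inf, Inf, rel.tol = 1e-10)$value
      row <- cts[cts$stratum == s$id & cts$level == lv, ]
      expect_equal(row$survived + row$died, n_samp, tolerance = 1e-7)
      expect_equal(row$died, d_samp, tolerance = 1e-7)
    }
  }
})

test_that("stochastic latent-health sampling shows the collider bias at scale", {
  sel <- selection_spec("latent_health", a0 = 0, a1 = 0.5, a1_exposed = 1.5,
                        b1 = -1)
  pair <- simulate_pair(fx$table2_population, sel, mode = "stochastic",
                        n = 200000, seed = 21)
  pop_rr <- vapply(summarize_cohort(pair$population),
                   function(s) s$levels$rr[2], numeric(1))
  sam_rr <- vapply(summarize_cohort(pair$sample),
                   function(s) s$levels$rr[2], numeric(1))
  expect_true(all(sam_rr < pop_rr))
})

test_that("person-period simulation matches its closed-form one-period rate", {
  n <- 20000
  pp <- simulate_person_periods(n, 1, intercept = -1.2, seed = 5)
  p <- 1 - exp(-exp(-1.2))
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(pp$died) - p), 3 * se)
})

test_that("person-period tables respect the at-risk structure", {
  pp <- simulate_person_periods(500, 6, intercept = -0.8,
                                exposure_coef = log(2), re_sd = 0.5,
                                n_groups = 5, entry = "staggered", seed = 9)
  by_subj <- split(pp, pp$subject)
  for (d in by_subj) {
    expect_true(all(diff(d$period) == 1))
    expect_equal(d$period[1], d$entry_period[1])
    expect_true(all(d$died[-nrow(d)] == 0))  # no rows after the death row
  }
  # staggered entry really starts groups late
  expect_gt(max(pp$entry_period), 1)
  expect_error(simulate_person_periods(10, 2, intercept = Inf, seed = 1),
               "finite")
})
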