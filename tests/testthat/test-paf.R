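fx <- paf_fixtures()

test_that("the two-level PAF formulas match the worked stratum values", {
  # black stratum of the hypothetical cohort, both routes
  expect_equal(round_half_up(paf_pd(0.5, 1.86), 3), 0.231)
  expect_equal(round_half_up(paf_pe(0.35, 1.86), 3), 0.231)
  # population black stratum under selection scenario
  expect_equal(round_half_up(paf_pd(0.538, 2.17), 3), 0.290)
  # null effect and no exposure
  expect_equal(paf_pd(0.7, 1), 0)
  expect_equal(paf_pe(0, 5), 0)
  # population white stratum (full-precision RR 0.5/0.15625 = 3.2)
  expect_equal(round_half_up(paf_pe(0.2, 3.2), 3), 0.306)
})

test_that("formula domains are enforced and protective exposures warn", {
  expect_error(paf_pd(0.5, 0), "RR must be positive")
  expect_error(paf_pd(1.2, 2), "\\[0, 1\\]")
  expect_error(paf_pe(-0.1, 2), "\\[0, 1\\]")
  expect_warning(neg <- paf_pd(0.5, 0.5), "protective")
  expect_lt(neg, 0)
})

test_that("multi-level formulas reproduce the two-level smoking PAF and reduce correctly", {
  expect_equal(round_half_up(paf_pd_multilevel(c(0.352, 0.338),
                                               c(1.489, 1.524)), 3), 0.232)
  expect_equal(round_half_up(paf_pe_multilevel(c(0.308, 0.289),
                                               c(1.489, 1.524)), 3), 0.232)
  # single non-reference level reduces exactly to the two-level formulas
  expect_identical(paf_pd_multilevel(0.4, 1.7), paf_pd(0.4, 1.7))
  expect_identical(paf_pe_multilevel(0.3, 2.2), paf_pe(0.3, 2.2))
  # null effects
  expect_equal(paf_pd_multilevel(c(0.3, 0.2), c(1, 1)), 0)
  expect_equal(paf_pe_multilevel(c(0, 0), c(2, 3)), 0)
  expect_error(paf_pd_multilevel(c(0.6, 0.6), c(2, 2)), "sum to more than 1")
})

test_that("weighted-sum standardization recovers the confounding-corrected PAF", {
  coh <- fx$table1
  pafs <- vapply(summarize_cohort(coh),
                 function(s) stratum_paf(s, "pd")$value, numeric(1))
  res <- weighted_sum_paf(pafs, death_share_weights(coh))
  expect_equal(round_half_up(res$value, 3), 0.222)
  expect_equal(res$value, sum(res$weights * res$stratum_values),
               tolerance = 1e-12)

  # weight invariance when stratum PAFs are identical
  same <- weighted_sum_paf(c(a = 0.4, b = 0.4), c(a = 0.9, b = 0.1))
  expect_equal(same$value, 0.4)

  expect_error(weighted_sum_paf(c(a = 0.1), c(b = 1)), "different strata")
  expect_error(weighted_sum_paf(c(a = 0.1, b = 0.2), c(a = 0.6, b = 0.6)),
               "sum to 1")
})

test_that("replication mode reproduces rounded-intermediate arithmetic", {
  res <- weighted_sum_paf(c(black = 0.2899408, white = 0.3055556),
                          c(black = 0.273, white = 0.727),
                          mode = "replication")
  # 0.290 * 0.273 + 0.306 * 0.727
  expect_equal(round_half_up(res$value, 3), 0.302)
  full <- weighted_sum_paf(c(black = 0.2899408, white = 0.3055556),
                           c(black = 0.273, white = 0.727))
  expect_equal(round_half_up(full$value, 3), 0.301)
})

test_that("counterfactual PAF matches the excess-death computation", {
  cf <- counterfactual_paf(fx$table1)
  expect_equal(round_half_up(cf$value, 3), 0.222)
  tab <- cf$details$table
  expect_equal(round_half_up(tab$counterfactual_died[tab$stratum == "black"], 0), 231)
  expect_equal(tab$counterfactual_died[tab$stratum == "white"], 625)
  expect_equal(cf$details$observed_deaths, 1100)

  # no exposure effect -> no attributable deaths
  flat <- cohort(data.frame(stratum = "s", level = c("a", "b"),
                            survived = c(90, 45), died = c(10, 5)))
  expect_equal(counterfactual_paf(flat)$value, 0)

  # population scenario: true PAF 0.301
  pop <- expected_counts(fx$table2_population)
  expect_equal(round_half_up(counterfactual_paf(pop)$value, 3), 0.301)
})

test_that("pd- and pe-based PAFs coincide within any internally consistent stratum", {
  set.seed(7)
  for (i in 1:50) {
    coh <- random_cohort(n_strata = 1, n_levels = 2)
    s <- summarize_stratum(coh)
    # random tables may carry protective exposures; the identity still holds
    suppressWarnings(
      expect_equal(stratum_paf(s, "pd")$value, stratum_paf(s, "pe")$value,
                   tolerance = 1e-12)
    )
  }
})

test_that("counterfactual PAF equals the death-weighted sum of stratum pd-PAFs", {
  set.seed(8)
  for (i in 1:50) {
    coh <- random_cohort()
    pafs <- suppressWarnings(
      vapply(summarize_cohort(coh),
             function(s) stratum_paf(s, "pd")$value, numeric(1))
    )
    ws <- weighted_sum_paf(pafs, death_share_weights(coh))
    expect_equal(counterfactual_paf(coh)$value, ws$value, tolerance = 1e-12)
  }
})

test_that("PAF formulas are monotone and bounded for harmful exposures", {
  pd_grid <- seq(0, 1, by = 0.1)
  rr_grid <- c(1, 1.5, 2, 5, 20)
  for (rr in rr_grid) {
    vals <- vapply(pd_grid, paf_pd, numeric(1), rr = rr)
    expect_true(all(diff(vals) >= 0))
    expect_true(all(vals >= 0 & vals <= pd_grid))
    vals_pe <- vapply(pd_grid, paf_pe, numeric(1), rr = rr)
    expect_true(all(diff(vals_pe) >= 0))
    expect_true(all(vals_pe >= 0 & vals_pe < 1))
  }
  for (p in c(0.2, 0.5, 0.9)) {
    expect_true(all(diff(vapply(rr_grid, paf_pd, numeric(1), pd = p)) >= 0))
    expect_true(all(diff(vapply(rr_grid, paf_pe, numeric(1), pe = p)) >= 0))
  }
})

test_that("stratified risk ratios: Mantel-Haenszel and death-weighted averaging", {
  expect_equal(round_half_up(unname(standardized_rr(fx$table1)), 3), 2.213)
  expect_equal(round_half_up(unname(
    standardized_rr(fx$table1, "death_weighted")), 3), 2.252)

  # single stratum: both methods return that stratum's RR
  one <- cohort(data.frame(stratum = "s", level = c("a", "b"),
                           survived = c(80, 60), died = c(20, 40)))
  rr <- summarize_stratum(one)$levels$rr[2]
  expect_equal(unname(standardized_rr(one)), rr)
  expect_equal(unname(standardized_rr(one, "death_weighted")), rr)

  # identical strata: MH equals the crude RR
  twin <- cohort(data.frame(stratum = rep(c("s1", "s2"), each = 2),
                            level = rep(c("a", "b"), 2),
                            survived = c(80, 60, 80, 60),
                            died = c(20, 40, 20, 40)))
  crude <- summarize_stratum(aggregate(twin))$levels$rr[2]
  expect_equal(unname(standardized_rr(twin)), crude)
})

test_that("proportionate bias is the signed relative error", {
  expect_equal(round_half_up(proportionate_bias(0.263, 0.301), 3), -0.126)
  expect_equal(round_half_up(proportionate_bias(0.289, 0.326), 3), -0.113)
  expect_equal(proportionate_bias(0.4, 0.4), 0)
  expect_error(proportionate_bias(0.1, 0), "non-zero")
})

test_that("externally adjusted RRs repair the risk ratio but not a biased pd", {
  sample_cohort <- fx$table1
  pop_rrs <- data.frame(stratum = c("black", "white"), level = "smoker",
                        rr = c(0.5 / (150 / 650), 0.5 / (500 / 3200)))
  adj_pd <- paf_from_adjusted_rrs(sample_cohort, pop_rrs, "pd")
  # biased sample pd (0.50, 0.375) with the true RRs (13/6, 3.2)
  expect_equal(unname(adj_pd$stratum_values),
               c(0.5 * (1 - 6 / 13), 0.375 * (1 - 1 / 3.2)),
               tolerance = 1e-12)
  adj_pe <- paf_from_adjusted_rrs(sample_cohort, pop_rrs, "pe")
  # sample pe is unbiased, so the stratum PAFs are the true ones
  expect_equal(round_half_up(unname(adj_pe$stratum_values), 3),
               c(0.290, 0.306))
  # and the pd route lands below the pe route
  expect_lt(adj_pd$value, adj_pe$value)

  null_rrs <- data.frame(stratum = c("black", "white"), level = "smoker", rr = 1)
  expect_equal(paf_from_adjusted_rrs(sample_cohort, null_rrs, "pd")$value, 0)
  expect_equal(paf_from_adjusted_rrs(sample_cohort, null_rrs, "pe")$value, 0)

  expect_error(
    paf_from_adjusted_rrs(sample_cohort,
                          data.frame(stratum = "black", level = "smoker", rr = 2)),
    "missing or duplicated"
  )
})

test_that("PAF results serialize to JSON with provenance", {
  res <- cohort_paf(fx$table1, "pd")
  parsed <- jsonlite::fromJSON(paf_result_json(res))
  expect_equal(parsed$value, res$value)
  expect_identical(parsed$scope, "weighted_sum")
  expect_identical(parsed$formula, "pd")
  expect_named(parsed$weights, c("black", "white"))
})
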