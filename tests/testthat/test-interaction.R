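test_that("mass-to-molar conversion reproduces printed dose pairs", {
  res_mm <- 228.25   # resveratrol, g/mol
  cddp_mm <- 300.05  # cisplatin, g/mol
  pairs <- rbind(
    c(24, res_mm, 105.15), c(12, res_mm, 52.57), c(2.5, res_mm, 10.95),
    c(80, res_mm, 350.50), c(21.06, res_mm, 92.27),
    c(9, cddp_mm, 30.00), c(4.5, cddp_mm, 15.00), c(4.98, cddp_mm, 16.60),
    c(10, cddp_mm, 33.33))
  for (i in seq_len(nrow(pairs)))
    expect_lt(abs(mass_to_molar(pairs[i, 1], pairs[i, 2]) - pairs[i, 3]),
              0.02)
  expect_equal(mass_to_molar(0, res_mm), 0)
  expect_error(mass_to_molar(1, 0), "molar mass")
  expect_error(mass_to_molar(-1, 10), ">= 0")
})

test_that("CDI classifies by the combined-over-product ratio", {
  # ratio > 1: antagonism under the additivity model
  m <- combination_measurement(0.605, 0.605, 0.88, "inhibition")
  r <- cdi_additivity(m)
  expect_equal(r$statistic, 0.88 / 0.605^2, tolerance = 1e-12)
  expect_gt(r$statistic, 2.3); expect_lt(r$statistic, 2.5)
  expect_equal(r$call, "antagonism")

  # exact product: additivity
  m2 <- combination_measurement(0.5, 0.8, 0.4, "viability")
  expect_equal(cdi_additivity(m2)$statistic, 1)
  expect_equal(cdi_additivity(m2)$call, "additivity")

  # hand arithmetic: 0.3 / (0.5 * 0.8) = 0.75 -> synergy
  m3 <- combination_measurement(0.5, 0.8, 0.3, "viability")
  expect_equal(cdi_additivity(m3)$statistic, 0.75)
  expect_equal(cdi_additivity(m3)$call, "synergy")

  expect_error(cdi_additivity(combination_measurement(0, 0.5, 0.2)),
               "undefined")

  # the ratio is not scale-invariant and must not be silently normalised
  scaled <- combination_measurement(0.25, 0.4, 0.15, "viability")
  expect_false(isTRUE(all.equal(cdi_additivity(scaled)$statistic,
                                cdi_additivity(m3)$statistic)))
})

test_that("Bliss independence compares against 1 - (1-Pa)(1-Pb)", {
  m <- combination_measurement(0.605, 0.605, 0.88, "inhibition")
  r <- bliss_independence(m)
  expect_equal(r$expected, 1 - (1 - 0.605)^2, tolerance = 1e-12)
  expect_equal(round(r$expected, 2), 0.84)
  expect_equal(r$call, "synergy")   # observed 0.88 above expected 0.84

  expect_equal(bliss_independence(
    combination_measurement(0.5, 0.6, 0.8, "inhibition"))$expected, 0.8)
  r0 <- bliss_independence(combination_measurement(0, 0, 0.2, "inhibition"))
  expect_equal(r0$expected, 0)
  expect_equal(r0$call, "synergy")

  expect_error(bliss_independence(
    combination_measurement(0.4, 0.4, 0.9, "viability")), "to_inhibition")
})

test_that("HSA compares against the better single agent", {
  r <- hsa_independence(combination_measurement(0.7, 0.5, 0.88, "inhibition"))
  expect_equal(r$expected, 0.7)
  expect_equal(r$call, "synergy")
  expect_equal(hsa_independence(
    combination_measurement(0.6, 0.4, 0.6, "inhibition"))$call,
    "no-interaction")
  expect_equal(hsa_independence(
    combination_measurement(0.6, 0.4, 0.4, "inhibition"))$call,
    "antagonism")
  expect_error(hsa_independence(
    combination_measurement(0.4, 0.4, 0.9, "viability")), "to_inhibition")
})

test_that("Bliss and HSA expectations obey their algebraic relations", {
  grid <- seq(0, 1, by = 0.1)
  for (pa in grid) for (pb in grid) {
    m <- combination_measurement(pa, pb, 0.5, "inhibition")
    bl <- bliss_independence(m)$expected
    hs <- hsa_independence(m)$expected
    expect_equal(bl, pa + pb - pa * pb, tolerance = 1e-12)
    expect_gte(bl, max(pa, pb) - 1e-12)
    expect_lte(bl, 1)
    expect_lte(hs, bl + 1e-12)      # HSA expectation never exceeds Bliss
    # symmetry in (pa, pb)
    m_swap <- combination_measurement(pb, pa, 0.5, "inhibition")
    expect_equal(bliss_independence(m_swap)$expected, bl, tolerance = 1e-12)
  }
})

test_that("to_inhibition complements responses and is an involution", {
  m <- combination_measurement(0.88, 0.7, 0.12, "viability")
  inh <- to_inhibition(m)
  expect_equal(inh$response_kind, "inhibition")
  expect_equal(inh$pa, 0.12)
  expect_equal(inh$pab, 0.88)
  back <- to_inhibition(inh)
  expect_equal(back[c("pa", "pb", "pab", "response_kind")],
               m[c("pa", "pb", "pab", "response_kind")])
  all1 <- to_inhibition(combination_measurement(1, 1, 1, "viability"))
  expect_equal(c(all1$pa, all1$pb, all1$pab), c(0, 0, 0))
})

test_that("the three-model report reaches a 2-of-3 consensus", {
  # inhibition data where the CDI ratio flags antagonism while the two
  # independence models both flag synergy
  m <- combination_measurement(0.605, 0.605, 0.88, "inhibition")
  rep <- interaction_report(m)
  expect_equal(rep$additivity_cdi$call, "antagonism")
  expect_equal(rep$statistical_independence$call, "synergy")
  expect_equal(rep$pharmacological_independence$call, "synergy")
  expect_equal(rep$consensus, "synergy")

  # all-boundary case: everything no-interaction/additive
  m2 <- combination_measurement(1, 1, 1, "inhibition")
  rep2 <- interaction_report(m2)
  expect_equal(rep2$consensus, "no-interaction")

  # strong antagonism in every model: combined worse than either single
  # agent yet above the viability product
  m3 <- combination_measurement(0.6, 0.6, 0.5, "inhibition")
  rep3 <- interaction_report(m3)
  expect_equal(unname(vapply(rep3[1:3], `[[`, "", "call")),
               rep("antagonism", 3))
  expect_equal(rep3$consensus, "antagonism")

  # viability input: CDI on viability, Bliss/HSA on the complement
  mv <- combination_measurement(0.4, 0.4, 0.12, "viability")
  repv <- interaction_report(mv)
  expect_equal(repv$additivity_cdi$statistic, 0.12 / 0.16, tolerance = 1e-12)
  expect_equal(repv$statistical_independence$expected, 0.84, tolerance = 1e-12)
})

test_that("4PL fitting recovers noise-free parameters to 0.1%", {
  conc <- c(2.5, 5, 10, 20, 40, 80)
  truth <- function(c, ic50 = 21.06, hill = 1.5, top = 1, bottom = 0.05)
    bottom + (top - bottom) / (1 + (c / ic50)^hill)
  fit <- fit_ic50_4pl(dose_response_table(conc, truth(conc)))
  expect_lt(abs(fit$ic50 - 21.06) / 21.06, 0.001)
  expect_equal(fit$hill, 1.5, tolerance = 1e-3)
  expect_equal(fit$unit, "ug/mL")
})

test_that("4PL fitting rejects degenerate and flags non-monotone input", {
  conc <- c(1, 2, 4, 8, 16)
  expect_error(fit_ic50_4pl(dose_response_table(conc, rep(0.5, 5))),
               "degenerate|constant")
  expect_error(fit_ic50_4pl(dose_response_table(c(1, 1, 2, 2),
                                                c(1, 0.9, 0.5, 0.4))),
               "4 distinct")
  expect_warning(fit_ic50_4pl(dose_response_table(
    conc, c(0.9, 0.2, 0.8, 0.1, 0.85))), "monotone")
})

test_that("median 4PL IC50 error stays below 10% at 5% noise", {
  conc <- rep(c(2.5, 5, 10, 20, 40, 80), each = 3)
  truth <- function(c) 0.05 + 0.95 / (1 + (c / 21.06)^1.5)
  set.seed(99)
  errs <- replicate(60, {
    r <- pmin(pmax(truth(conc) + rnorm(length(conc), 0, 0.05), 0), 1)
    f <- suppressWarnings(fit_ic50_4pl(
      dose_response_table(conc, r, replicate = rep(1:3, 6))))
    abs(f$ic50 - 21.06) / 21.06
  })
  expect_lt(median(errs), 0.10)
})
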