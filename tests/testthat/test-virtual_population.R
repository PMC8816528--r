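test_that("sampling is seed-reproducible", {
  spec <- population_spec("ckd_severe")
  a <- sample_population(spec, 20, seed = 123)
  b <- sample_population(spec, 20, seed = 123)
  expect_identical(a, b)
  expect_identical(sample_subject(spec, 7), sample_subject(spec, 7))
})

test_that("severity classes partition the BSA-normalised GFR scale", {
  sev <- sample_population(population_spec("ckd_severe"), 300, seed = 2)
  mod <- sample_population(population_spec("ckd_moderate"), 300, seed = 2)
  expect_true(all(subject_field(sev, "gfr_bsa") < 30))
  expect_true(all(subject_field(sev, "gfr_bsa") >= 15))
  expect_true(all(subject_field(mod, "gfr_bsa") >= 30))
  expect_true(all(subject_field(mod, "gfr_bsa") < 60))
})

test_that("population medians match the calibration targets", {
  healthy <- sample_population(population_spec("healthy"), 1000, seed = 11)
  g <- subject_field(healthy, "gfr")
  expect_equal(median(g), 114, tolerance = 0.08)
  expect_equal(median(subject_field(healthy, "hsa")), 46.4, tolerance = 0.05)

  severe <- sample_population(population_spec("ckd_severe"), 1000, seed = 11)
  expect_equal(median(subject_field(severe, "gfr")), 21.0, tolerance = 0.1)
  expect_equal(median(subject_field(severe, "hsa")), 36.7, tolerance = 0.06)
})

test_that("sampled moments converge to the specified means and CVs", {
  healthy <- sample_population(population_spec("healthy"), 5000, seed = 3)
  ptc <- subject_field(healthy, "ptcpgk")
  oat <- subject_field(healthy, "oat1_rel")
  expect_equal(mean(ptc), 60, tolerance = 0.03)
  expect_equal(sd(ptc) / mean(ptc), 0.30, tolerance = 0.08)
  expect_equal(mean(oat), 1, tolerance = 0.05)
  expect_equal(sd(oat) / mean(oat), 0.60, tolerance = 0.10)
})

test_that("zero variance collapses the population onto one subject", {
  subj <- sample_population(degenerate_spec(), 5, seed = 9)
  for (field in c("gfr", "body_weight", "kidney_weight", "ptcpgk",
                  "oat1_rel", "hsa", "urine_flow"))
    expect_equal(diff(range(subject_field(subj, field))), 0)
})

test_that("CKD scenarios rescale the secretion machinery per Table of multipliers", {
  s <- sample_subject(degenerate_spec(), 5)
  expect_equal(apply_ckd_scenario(
    s, ckd_scenario("inh_ptcpgk", "severe"))$ptcpgk, s$ptcpgk * 10.2 / 60)
  expect_equal(apply_ckd_scenario(
    s, ckd_scenario("inh_ptcpgk", "moderate"))$ptcpgk, s$ptcpgk * 21 / 60)
  expect_equal(apply_ckd_scenario(
    s, ckd_scenario("inh_oat1", "moderate"))$oat1_rel, s$oat1_rel * 0.35)
  both <- apply_ckd_scenario(s, ckd_scenario("inh_oat1_mate", "severe"))
  expect_equal(both$oat1_rel, s$oat1_rel * 0.17)
  expect_equal(both$mate_rel, s$mate_rel * 0.17)
  ur <- apply_ckd_scenario(s, ckd_scenario("inh_ptcpgk_uremic", "severe"))
  expect_equal(ur$oat1_activity_scale, 0.41)
  expect_equal(ur$ptcpgk, s$ptcpgk * 10.2 / 60)
  ur_m <- apply_ckd_scenario(s, ckd_scenario("inh_ptcpgk_uremic", "moderate"))
  expect_equal(ur_m$oat1_activity_scale, 0.73)
  def <- apply_ckd_scenario(s, ckd_scenario("default", "severe"))
  expect_equal(def$ptcpgk, s$ptcpgk)
  expect_error(ckd_scenario("no_such"), "arg")
})

test_that("geriatric covariates lower filtration and cardiac output as calibrated", {
  healthy <- sample_population(population_spec("healthy"), 1500, seed = 4)
  geri <- sample_population(population_spec("geriatric"), 1500, seed = 5)
  gfr_ratio <- median(subject_field(geri, "gfr")) /
    median(subject_field(healthy, "gfr"))
  co_ratio <- median(subject_field(geri, "cardiac_output")) /
    median(subject_field(healthy, "cardiac_output"))
  expect_equal(gfr_ratio, 0.55, tolerance = 0.12)
  expect_equal(co_ratio, 0.81, tolerance = 0.06)
  ## kidney weight and urine flow are age-invariant
  expect_equal(median(subject_field(geri, "kidney_weight")),
               median(subject_field(healthy, "kidney_weight")),
               tolerance = 0.06)
  expect_equal(median(subject_field(geri, "urine_flow")),
               median(subject_field(healthy, "urine_flow")),
               tolerance = 0.05)
})

test_that("re-ageing a subject is continuous at the geriatric boundary", {
  base <- sample_subject(population_spec("geriatric"), 21)
  same <- geriatric_covariates(base$age, base)
  expect_equal(same$gfr, base$gfr, tolerance = 1e-12)
  expect_equal(same$cardiac_output, base$cardiac_output, tolerance = 1e-12)
  older <- geriatric_covariates(95, base)
  expect_lt(older$gfr, base$gfr)
  expect_equal(older$kidney_weight, base$kidney_weight)
  expect_error(geriatric_covariates(50, base), "65-95")
})

test_that("diagnostics flag gaps in pooled multimodal populations", {
  healthy <- sample_population(population_spec("healthy"), 300, seed = 6)
  severe <- sample_population(population_spec("ckd_severe"), 300, seed = 6)
  diag <- population_diagnostics(c(healthy, severe))
  gfr_gaps <- diag$gaps[diag$gaps$parameter == "gfr_bsa", ]
  expect_gt(nrow(gfr_gaps), 0)
  ## the empty band sits between the severe cap (30) and healthy floor (90)
  expect_gt(gfr_gaps$gap_low[1], 25)
  expect_lt(gfr_gaps$gap_high[1], 95)

  ## a single smooth population has no GFR gap
  diag_h <- population_diagnostics(healthy)
  expect_equal(nrow(diag_h$gaps[diag_h$gaps$parameter == "gfr_bsa", ]), 0)
})

test_that("diagnostics mark degenerate inputs instead of guessing", {
  subj <- sample_population(degenerate_spec(), 10, seed = 1)
  diag <- population_diagnostics(subj)
  degen <- diag$summary$degenerate[diag$summary$parameter == "gfr"]
  expect_true(degen)
  expect_true(all(is.na(diag$correlations["gfr", ])))
})
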