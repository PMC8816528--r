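test_that("flow profile honours GFR, urine flow and monotonicity", {
  fp <- build_flow_profile(gfr = 120, urine_flow = 1)
  expect_equal(fp$q_in[["PT1"]], 120)
  expect_equal(fp$q_out[["MCD"]], 1)
  expect_true(all(diff(fp$q_out) <= 0))

  ## identical upstream fractions, only the MCD outflow differs
  fp05 <- build_flow_profile(120, 0.5)
  expect_equal(fp$q_out[-7L], fp05$q_out[-7L])
  expect_equal(fp05$q_out[["MCD"]], 0.5)

  expect_error(build_flow_profile(120, 130), "below GFR")
  expect_error(build_flow_profile(
    120, 1, fractions = c(PT1 = 0.3, PT2 = 0.55, PT3 = 0.33, LoH = 0.2,
                          DT = 0.1, CCD = 0.05)),
    "non-increasing")
})

test_that("low-GFR profiles keep water reabsorption non-negative", {
  ## preserved urine output with severe disease: outflow floor kicks in
  fp <- build_flow_profile(gfr = 18, urine_flow = 1.4)
  expect_true(all(diff(fp$q_out) <= 0))
  expect_gt(fp$q_out[["CCD"]], 1.4)
  expect_error(build_flow_profile(gfr = 3, urine_flow = 1.4), "too close")
})

test_that("steady-state oracle solves the nephron chain", {
  fp <- build_flow_profile(120, 1)
  ## all drug entering at PT1 ends in urine at rate/urine-flow concentration
  conc <- steady_state_luminal_oracle(fp, c(PT1 = 60))
  expect_equal(conc[["MCD"]], 60 / 0.06)
  ## flow-ratio identity along the chain
  expect_equal(conc[["MCD"]] / conc[["PT1"]],
               fp$q_out[["PT1"]] / fp$q_out[["MCD"]])
  ## halving urine flow exactly doubles the MCD concentration
  fp_half <- build_flow_profile(120, 0.5)
  conc_half <- steady_state_luminal_oracle(fp_half, c(PT1 = 60))
  expect_equal(conc_half[["MCD"]], 2 * conc[["MCD"]])
})

test_that("kidney fluxes vanish for an all-zero state", {
  fp <- build_flow_profile(114, 1)
  st <- list(lumen = setNames(numeric(7), c("PT1", "PT2", "PT3", "LoH", "DT",
                                            "CCD", "MCD")),
             cell = 0, c_plasma = 0)
  fl <- kidney_fluxes(st, reference_subject(), gcv, fp)
  expect_equal(fl$filtration, 0)
  expect_equal(fl$uptake, 0)
  expect_equal(unname(fl$dlumen), numeric(7))
  expect_equal(fl$durine, 0)
})

test_that("fast apical efflux drains the cell pool: secretion tracks uptake", {
  ## quasi-steady-state algebra of the two-step secretion chain: the cell
  ## amount that balances uptake is A = uptake * v_cell / CL_eff, which
  ## vanishes as clint_mate grows, while the efflux rate equals the uptake
  ## rate exactly at that amount
  ref <- reference_subject()
  fp <- build_flow_profile(ref$gfr, ref$urine_flow)
  lum <- setNames(rep(0.01, 7), c("PT1", "PT2", "PT3", "LoH", "DT", "CCD",
                                  "MCD"))
  amounts <- vapply(c(60, 6000, 6e5), function(mate) {
    drug <- gcv
    drug$clint_mate <- mate
    cl_eff <- mate * ref$ptcpgk * ref$kidney_weight * 6e-5
    v_cell <- ref$ptcpgk * ref$kidney_weight * 5e-6
    probe <- kidney_fluxes(list(lumen = lum, cell = 0, c_plasma = 5),
                           ref, drug, fp)
    a_qss <- probe$uptake * v_cell / cl_eff
    fl <- kidney_fluxes(list(lumen = lum, cell = a_qss, c_plasma = 5),
                        ref, drug, fp)
    expect_equal(fl$efflux, fl$uptake, tolerance = 1e-12)
    expect_equal(fl$dcell, 0, tolerance = 1e-9)
    a_qss
  }, numeric(1L))
  ## steady-state cell amount -> 0 as the efflux clearance -> infinity
  expect_true(all(diff(amounts) < 0))
  expect_lt(amounts[3L], amounts[1L] / 1e3)
})

test_that("constant infusion reaches the analytic luminal steady state", {
  ## 100 mg/h IV infusion at steady state excretes fe x 100 mg/h; with
  ## 1 mL/min urine flow the MCD concentration is fe*100/0.06 mg/L
  ref <- reference_subject()
  reg <- dose_regimen("iv_infusion", 100 * 96, infusion_duration = 96)
  sim <- simulate_subject(ref, gcv, reg, duration = 96)
  n <- length(sim$time)
  mcd_ss <- unname(sim$segment_conc[n, "MCD"])
  fe <- attr(gcv, "calibration")$fe
  expect_equal(mcd_ss, fe * 100 / 0.06, tolerance = 0.01)
  expect_equal(mcd_ss, 0.88 * 100 / 0.06, tolerance = 0.015)

  ## every segment matches the independent steady-state chain oracle to 0.1%
  fp <- build_flow_profile(ref$gfr, ref$urine_flow)
  cp <- sim$plasma_conc[n]
  fu <- 0.98
  filt <- fp$gfr * 0.06 * fu * cp
  cl <- gcv$clint_oat1 * ref$ptcpgk * ref$kidney_weight * 6e-5
  upt <- cl * fu * cp
  entry <- c(PT1 = filt + 0.15 * upt, PT2 = 0.50 * upt, PT3 = 0.35 * upt)
  oracle <- steady_state_luminal_oracle(fp, entry)
  expect_equal(unname(sim$segment_conc[n, ]), unname(oracle),
               tolerance = 1e-3)
})

test_that("luminal concentration is non-decreasing along the nephron", {
  sim <- simulate_subject(reference_subject(), gcv, oral_900, duration = 48)
  cmax <- apply(sim$segment_conc, 2, max)
  expect_true(all(diff(cmax) > 0))
})
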