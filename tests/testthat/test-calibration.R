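ctx_small <- calibrationContext(n_trials = 1, n_per_trial = 6, seed = 17)

test_that("acceptance window is inclusive at both printed boundaries", {
  expect_true(withinWindow(1, 1))
  expect_true(withinWindow(1.25, 1))
  expect_true(withinWindow(0.8, 1))
  expect_false(withinWindow(2, 1))
  expect_false(withinWindow(0.79, 1))
  expect_true(withinWindow(1.9, 1, lo = 0.5, hi = 2))  # validation window
  expect_error(withinWindow(-1, 1), "positive")
  expect_error(withinWindow(1, 1, lo = 2, hi = 1), "ordered")
})

test_that("identical specs and profiles give an exposure ratio of exactly 1", {
  hv <- hvPopulationSpec()
  r <- predictAUCR(drugFixture("midazolam"), microdoseRegimen("midazolam"),
                   hv, hv, hvProf, hvProf, n_trials = 1, n_per_trial = 4,
                   seed = 3)
  expect_equal(r, 1, tolerance = 1e-12)
})

test_that("exposure-ratio directions: fu up lowers AUCR, uptake down raises it", {
  # ESRD physiology with unchanged abundances: higher fu of the CYP3A4
  # probe raises unbound clearance, so AUCR < 1
  prof_unchanged <- hvDmetProfile()
  prof_unchanged@label <- "ESRD"
  r_mdz <- predictAUCR(drugFixture("midazolam"), microdoseRegimen("midazolam"),
                       hvPopulationSpec(), esrdPopulationSpec(), hvProf,
                       prof_unchanged, n_trials = 1, n_per_trial = 6, seed = 3)
  expect_lt(r_mdz, 1)
  # OATP1B knocked down to 25%: uptake-limited statin AUCR > 1
  prof_oatp <- candidateEsrdProfile(hvProf, list(OATP1B = 0.25))
  r_ptv <- predictAUCR(drugFixture("pitavastatin"),
                       microdoseRegimen("pitavastatin"), hvPopulationSpec(),
                       esrdPopulationSpec(), hvProf, prof_oatp,
                       n_trials = 1, n_per_trial = 6, seed = 3)
  expect_gt(r_ptv, 1)
})

test_that("back-calculation recovers multipliers across the admissible range", {
  drug <- drugFixture("pitavastatin")
  reg <- microdoseRegimen("pitavastatin")
  for (truth in c(0.1, 0.5, 2)) {
    prof <- candidateEsrdProfile(ctx_small$profile_hv, list(OATP1B = truth))
    obs <- predictAUCR(drug, reg, ctx_small$hv_spec, ctx_small$esrd_spec,
                       ctx_small$profile_hv, prof, n_trials = 1,
                       n_per_trial = 6, seed = 17)
    est <- backcalcAbundance(drug, reg, "OATP1B", obs, ctx_small)
    expect_equal(est$multiplier, truth, tolerance = 0.01)
    expect_true(est$accepted)
  }
})

test_that("back-calculation is deterministic and recovers the identity", {
  drug <- drugFixture("midazolam")
  reg <- microdoseRegimen("midazolam")
  obs <- predictAUCR(drug, reg, ctx_small$hv_spec, ctx_small$esrd_spec,
                     ctx_small$profile_hv,
                     candidateEsrdProfile(ctx_small$profile_hv, list()),
                     n_trials = 1, n_per_trial = 6, seed = 17)
  e1 <- backcalcAbundance(drug, reg, "CYP3A4.liver", obs, ctx_small)
  e2 <- backcalcAbundance(drug, reg, "CYP3A4.liver", obs, ctx_small)
  expect_identical(e1$multiplier, e2$multiplier)
  expect_equal(e1$multiplier, 1, tolerance = 0.01)
})

test_that("an unattainable observed ratio raises a bracket error", {
  expect_error(
    backcalcAbundance(drugFixture("midazolam"), microdoseRegimen("midazolam"),
                      "CYP3A4.liver", 1000, ctx_small),
    "attainable")
})

test_that("protocol order matters: the BCRP estimate depends on fixing OATP1B first", {
  drug <- drugFixture("rosuvastatin")
  reg <- microdoseRegimen("rosuvastatin")
  truth <- list(OATP1B = 0.25, `BCRP.ileum` = 2, `OAT3.renal` = 0.246)
  prof <- candidateEsrdProfile(ctx_small$profile_hv, truth)
  obs <- predictAUCR(drug, reg, ctx_small$hv_spec, ctx_small$esrd_spec,
                     ctx_small$profile_hv, prof, n_trials = 1,
                     n_per_trial = 6, seed = 17)
  with_fix <- backcalcAbundance(drug, reg, "BCRP.ileum", obs, ctx_small,
                                fixed = list(OATP1B = 0.25,
                                             `OAT3.renal` = 0.246))
  expect_equal(with_fix$multiplier, 2, tolerance = 0.02)
  # without the uptake reduction fixed first, ileal efflux alone cannot
  # reproduce the observed ratio at all — the estimate is not just
  # different, the inversion has no root
  expect_error(
    backcalcAbundance(drug, reg, "BCRP.ileum", obs, ctx_small,
                      fixed = list(`OAT3.renal` = 0.246)),
    "attainable")
})

test_that("sequential calibration recovers a ground-truth profile end to end", {
  ctx <- calibrationContext(n_trials = 1, n_per_trial = 8, seed = 29)
  truth <- list(`CYP3A4.liver` = 1.0, `P-gp.jejunum` = 0.66, OATP1B = 0.25,
                `BCRP.ileum` = 2.0, `OAT3.renal` = 0.246)
  obs <- syntheticObservedAUCR(candidateEsrdProfile(ctx$profile_hv, truth), ctx)
  cal <- sequentialCalibration(obs, ctx)
  expect_true(all(cal$steps$accepted))
  expect_equal(cal$multipliers$`CYP3A4.liver`, 1.0, tolerance = 0.01)
  expect_equal(cal$multipliers$`P-gp.jejunum`, 0.66, tolerance = 0.01)
  expect_equal(cal$multipliers$OATP1B, 0.25, tolerance = 0.01)
  expect_equal(cal$multipliers$`BCRP.ileum`, 2.0, tolerance = 0.01)
  # the assembled profile carries the estimates into the printed cells
  expect_equal(profileEntry(cal$profile_esrd, "OATP1B3", "liver")[["EM/T"]],
               0.25, tolerance = 0.01)
  # a perturbed validation observation is rejected
  obs_bad <- obs
  obs_bad[["atorvastatin"]] <- 3 * obs[["atorvastatin"]]
  cal_bad <- sequentialCalibration(obs_bad, ctx)
  expect_false(cal_bad$steps$accepted[cal_bad$steps$drug == "atorvastatin"])
})

test_that("calibration aborts informatively when an observation is missing", {
  expect_error(sequentialCalibration(c(midazolam = 1), ctx_small),
               "no observed AUCR")
})
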