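test_that("healthy-volunteer profile holds the baseline abundances and scores", {
  p <- hvProf
  e <- profileEntry(p, "OATP1B1", "liver")
  expect_equal(e$abundance, 3.1)
  expect_equal(e[["EM/T"]], 0.584)
  expect_equal(e[["PM/T"]], 0.21)
  expect_equal(profileEntry(p, "BCRP", "ileum")$abundance, 0.78)
  expect_equal(profileEntry(p, "CYP3A4", "liver")$abundance, 120)
  expect_equal(profileEntry(p, "OAT3", "renal")[["EM/T"]], 1)
  expect_true(validObject(p))
})

test_that("ESRD profile applies the calibrated multipliers to the printed cells", {
  p <- esrdProf
  expect_equal(profileEntry(p, "OATP1B1", "liver")[["EM/T"]], 0.146)
  expect_equal(profileEntry(p, "OATP1B1", "liver")[["PM/T"]], 0.0525)
  expect_equal(profileEntry(p, "OATP1B1", "liver")[["UM/T"]], 0.2025)
  expect_equal(profileEntry(p, "OATP1B3", "liver")[["EM/T"]], 0.25)
  expect_equal(profileEntry(p, "P-gp", "jejunum")[["EM/T"]], 0.66)
  expect_equal(profileEntry(p, "BCRP", "ileum")$abundance, 1.56)
  expect_equal(profileEntry(p, "OAT3", "renal")[["EM/T"]], 0.246)
  # unchanged entries
  expect_equal(profileEntry(p, "CYP3A4", "liver")[["EM/T"]], 1)
  expect_equal(profileEntry(p, "BCRP", "liver")$abundance, 0.103)
  expect_equal(profileEntry(p, "P-gp", "liver")[["EM/T"]], 1)
})

test_that("OATP1B1 and OATP1B3 multipliers are locked together", {
  p <- applyAbundanceMultiplier(hvProf, "OATP1B", "liver", 0.5)
  expect_equal(profileEntry(p, "OATP1B1", "liver")[["EM/T"]], 0.584 * 0.5)
  expect_equal(profileEntry(p, "OATP1B3", "liver")[["EM/T"]], 0.5)
  p2 <- applyAbundanceMultiplier(hvProf, "OATP1B3", "liver", 2)
  expect_equal(profileEntry(p2, "OATP1B1", "liver")[["EM/T"]], 0.584 * 2)
  expect_error(applyAbundanceMultiplier(hvProf, "UGT1A1", "liver", 1), "no profile entry")
  expect_error(applyAbundanceMultiplier(hvProf, "CYP3A4", "liver", -1), "non-negative")
})

test_that("effective intrinsic clearance scales linearly and halves at Iu = Ki", {
  ind <- refInd()
  d <- drugModel("toy", mw = 100, fu_hv = 0.5, binding_protein = "none",
                 clint = list("CYP3A4.liver" = 10))
  expect_equal(effectiveClint(d, "CYP3A4", "liver", toyProfile(1, 1), ind), 10)
  expect_equal(effectiveClint(d, "CYP3A4", "liver", toyProfile(1, 0.25), ind), 2.5)
  expect_equal(effectiveClint(d, "CYP3A4", "liver", toyProfile(2, 0.25), ind), 5)
  inh <- new("InhibitorExposure", name = "i", iu = 3,
             ki = c("CYP3A4" = 3), mbi = list(), kdeg = 0.03)
  expect_equal(effectiveClint(d, "CYP3A4", "liver", toyProfile(1, 1), ind, inh), 5)
  expect_error(effectiveClint(d, "OAT3", "renal", toyProfile(), ind), "no clint")
})

test_that("ESRD/HV effective clearance ratio for hepatic OATP1B1 is 0.25", {
  ind <- refInd()
  d <- drugModel("toy", mw = 100, fu_hv = 0.5, binding_protein = "none",
                 clint = list("OATP1B1.liver" = 1))
  hv <- effectiveClint(d, "OATP1B1", "liver", hvProf, ind)
  es <- effectiveClint(d, "OATP1B1", "liver", esrdProf, ind)
  expect_equal(es / hv, 0.25, tolerance = 1e-12)
})

test_that("renal OAT3 clearance carries the individual secretory fraction", {
  d <- drugModel("toy", mw = 100, fu_hv = 0.5, binding_protein = "none",
                 clint = list("OAT3.renal" = 100))
  hv_ind <- refInd()
  expect_equal(effectiveClint(d, "OAT3", "renal", hvProf, hv_ind), 100 * 1.32)
  es_ind <- referenceIndividual("M", esrdPopulationSpec())
  expect_equal(effectiveClint(d, "OAT3", "renal", hvProf, es_ind),
               100 * 1.32 * es_ind@oat3_fraction)
})

test_that("mechanism-based inhibition attenuates by the steady-state enzyme balance", {
  inh <- inhibitorFixture("clarithromycin")
  m <- inh@mbi$CYP3A4
  expected <- inh@kdeg / (inh@kdeg + m$kinact * inh@iu / (m$KI + inh@iu))
  expect_equal(inhibitionFactor(inh, "CYP3A4"), expected, tolerance = 1e-12)
  expect_lt(inhibitionFactor(inh, "CYP3A4"), 0.1) # strong inactivator
  expect_identical(inhibitionFactor(NULL, "CYP3A4"), 1)
  expect_identical(inhibitionFactor(inh, "OAT3"), 1) # untargeted pathway
})
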