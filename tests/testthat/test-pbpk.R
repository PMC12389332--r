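test_that("iv bolus with one clearance matches the one-compartment closed form", {
  ind <- refInd()
  drug <- degenerateIvDrug(cl = 1, v = 10, individual = ind)
  sim <- simulateDrug(drug, ivBolus(10), ind, hvProf, t_end = 200)
  expect_equal(sim@conc$plasma[1], 1, tolerance = 1e-3)        # C0 = D/V
  nca <- ncaSummary(sim@t, sim@conc$plasma, 10)
  expect_equal(nca$auc_0_inf, 10, tolerance = 1e-3)            # D/CL
  expect_equal(nca$lambda_z, 0.1, tolerance = 1e-3)            # CL/V
  expect_equal(nca$cl_over_f, 1, tolerance = 1e-3)
  # pointwise against the analytic curve
  expect_equal(sim@conc$plasma, exp(-0.1 * sim@t), tolerance = 1e-3)
})

test_that("muscle as peripheral compartment matches the two-compartment closed form", {
  ind <- refInd()
  kp <- 4
  drug <- degenerateIvDrug(cl = 2, v = 10, individual = ind, kp_muscle = kp)
  p <- buildPbpkParams(drug, ind, hvProf)
  sim <- simulateDrug(drug, ivBolus(10), ind, hvProf, t_end = 120)
  ref <- twoCptIvBolus(sim@t, dose = 10, cl = 2, v1 = 10,
                       v2 = p[["Vm"]] * kp, q = p[["Q_m"]])
  expect_equal(sim@conc$plasma, ref, tolerance = 1e-3)
})

test_that("mass balance holds within 1e-6 for every fixture, route and regimen", {
  ind <- refInd()
  for (nm in c("midazolam", "dabigatran", "pitavastatin", "rosuvastatin",
               "atorvastatin")) {
    reg <- microdoseRegimen(nm)
    sim <- simulateDrug(drugFixture(nm), reg, ind, hvProf)
    expect_lt(massBalanceError(sim, reg), 1e-6)
    sim_e <- simulateDrug(drugFixture(nm), reg,
                          referenceIndividual("F", esrdPopulationSpec()),
                          esrdProf)
    expect_lt(massBalanceError(sim_e, reg), 1e-6)
  }
  md <- doseRegimen("oral", 10, n_doses = 4, interval = 24)
  sim_md <- simulateDrug(drugFixture("rosuvastatin"), md, ind, hvProf, t_end = 120)
  expect_lt(massBalanceError(sim_md, md), 1e-6)
})

test_that("the compiled and R reference right-hand sides agree", {
  ind <- refInd()
  for (nm in c("midazolam", "dabigatran", "rosuvastatin")) {
    reg <- microdoseRegimen(nm)
    sC <- simulateDrug(drugFixture(nm), reg, ind, hvProf)
    sR <- simulateDrug(drugFixture(nm), reg, ind, hvProf, engine = "R")
    expect_lt(max(abs(sC@conc$plasma - sR@conc$plasma)) / max(sC@conc$plasma), 1e-6)
  }
})

test_that("disposition is dose-linear", {
  ind <- refInd()
  d <- drugFixture("atorvastatin")
  s1 <- simulateDrug(d, doseRegimen("oral", 1), ind, hvProf)
  s2 <- simulateDrug(d, doseRegimen("oral", 2), ind, hvProf)
  expect_equal(2 * aucLinUpLogDown(s1@t, s1@conc$plasma),
               aucLinUpLogDown(s2@t, s2@conc$plasma), tolerance = 1e-6)
  expect_equal(2 * max(s1@conc$plasma), max(s2@conc$plasma), tolerance = 1e-6)
})

test_that("with every clearance off, nothing is eliminated except gut transit", {
  ind <- refInd()
  d <- drugModel("inert", mw = 100, fu_hv = 0.5, binding_protein = "none",
                 ka = 1, vss = 1, renal_filtration = FALSE)
  sim <- simulateDrug(d, doseRegimen("oral", 5), ind, hvProf)
  el <- sim@eliminated[nrow(sim@eliminated), ]
  expect_true(all(el[setdiff(names(el), "elim_fecal")] < 1e-9))
  # absorbed + fecal + in-transit = dose
  expect_lt(massBalanceError(sim, doseRegimen("oral", 5)), 1e-6)
})

test_that("AUC is monotone in elimination-pathway strength and intestinal efflux", {
  ind <- refInd()
  # hepatic CYP3A4 multiplier up => AUC down
  aucs <- vapply(c(0.25, 1, 4), function(m) {
    prof <- applyAbundanceMultiplier(hvProf, "CYP3A4", "liver", m)
    sim <- simulateDrug(drugFixture("midazolam"), microdoseRegimen("midazolam"),
                        ind, prof)
    aucLinUpLogDown(sim@t, sim@conc$plasma)
  }, numeric(1))
  expect_true(all(diff(aucs) < 0))
  # jejunal P-gp efflux clint up => bioavailable fraction (AUC) down
  aucs_eff <- vapply(c(0, 10, 40), function(cl) {
    d <- drugModel("effluxed", mw = 100, fu_hv = 0.5, binding_protein = "none",
                   ka = 0.5, vss = 1, cl_extra = 5, renal_filtration = FALSE,
                   clint = if (cl > 0) list("P-gp.jejunum" = cl) else list())
    sim <- simulateDrug(d, doseRegimen("oral", 5), ind, hvProf)
    aucLinUpLogDown(sim@t, sim@conc$plasma)
  }, numeric(1))
  expect_true(all(diff(aucs_eff) < 0))
})

test_that("reduced hepatic uptake raises plasma exposure of an OATP1B substrate", {
  ind <- refInd()
  d <- drugFixture("pitavastatin")
  reg <- microdoseRegimen("pitavastatin")
  hv <- simulateDrug(d, reg, ind, hvProf)
  prof_low <- applyAbundanceMultiplier(hvProf, "OATP1B", "liver", 0.25)
  low <- simulateDrug(d, reg, ind, prof_low)
  expect_gt(aucLinUpLogDown(low@t, low@conc$plasma),
            aucLinUpLogDown(hv@t, hv@conc$plasma))
})

test_that("the prodrug pathway responds to intestinal P-gp inhibition", {
  ind <- refInd()
  d <- drugFixture("dabigatran")
  reg <- microdoseRegimen("dabigatran")
  base <- simulateDrug(d, reg, ind, hvProf)
  inh <- simulateDrug(d, reg, ind, hvProf,
                      inhibitor = inhibitorFixture("itraconazole"))
  expect_gt(max(base@conc$plasma), 0)
  expect_gt(aucLinUpLogDown(inh@t, inh@conc$plasma),
            aucLinUpLogDown(base@t, base@conc$plasma))
})

test_that("population simulation bookkeeping, determinism and variability", {
  d <- drugFixture("midazolam")
  reg <- microdoseRegimen("midazolam")
  spec <- hvPopulationSpec()
  res <- populationSimulate(d, reg, spec, hvProf, n_trials = 2,
                            n_per_trial = 3, seed = 5, dt = 0.1)
  expect_equal(nrow(res$subjects), 6)
  expect_equal(nrow(res$trials), 2)
  res2 <- populationSimulate(d, reg, spec, hvProf, n_trials = 2,
                             n_per_trial = 3, seed = 5, dt = 0.1)
  expect_identical(res$summary, res2$summary)
  expect_gt(sd(res$subjects$auc) / mean(res$subjects$auc), 0)
})

test_that("simulation rejects invalid windows and zero-volume states", {
  ind <- refInd()
  expect_error(simulateDrug(drugFixture("midazolam"),
                            doseRegimen("oral", 1, n_doses = 2, interval = 24),
                            ind, hvProf, t_end = 12), "t_end")
})
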