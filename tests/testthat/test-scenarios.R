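test_that("a perpetrator without shared targets leaves exposure unchanged", {
  r <- ddiScenario(drugFixture("pitavastatin"), inhibitorFixture("ritonavir"),
                   microdoseRegimen("pitavastatin"), hvPopulationSpec(),
                   hvProf, n_trials = 1, n_per_trial = 4, seed = 2)
  expect_equal(r$aucr_w_wo, 1, tolerance = 1e-9)
  expect_equal(r$cmaxr_w_wo, 1, tolerance = 1e-9)
})

test_that("inhibitors raise exposure; interaction is amplified in ESRD", {
  # OATP1B inhibition at Iu = Ki on the uptake-limited statin
  inh <- inhibitorFixture("rifampin", iu = 0.5)
  r <- ddiScenario(drugFixture("pitavastatin"), inh,
                   microdoseRegimen("pitavastatin"), hvPopulationSpec(),
                   hvProf, n_trials = 1, n_per_trial = 4, seed = 2)
  expect_gt(r$aucr_w_wo, 1)
  # renal-compensation loss: rosuvastatin + rifampin, ESRD vs HV
  hv <- ddiScenario(drugFixture("rosuvastatin"), inhibitorFixture("rifampin"),
                    microdoseRegimen("rosuvastatin"), hvPopulationSpec(),
                    hvProf, n_trials = 1, n_per_trial = 6, seed = 2)
  es <- ddiScenario(drugFixture("rosuvastatin"), inhibitorFixture("rifampin"),
                    microdoseRegimen("rosuvastatin"), esrdPopulationSpec(),
                    esrdProf, n_trials = 1, n_per_trial = 6, seed = 2)
  expect_gte(es$aucr_w_wo, hv$aucr_w_wo)
  expect_gte(hv$aucr_w_wo, 1)
})

test_that("single-pathway liver-only inhibition approaches the 1 + Iu/Ki bound", {
  ind <- refInd()
  # uptake-limited: fu x CL_upt << Q_h, no passive back-flux
  d <- drugModel("uptake_only", mw = 300, fu_hv = 0.001,
                 binding_protein = "none", vss = 0.15, ps_liver = 1e-6,
                 clint = list("OATP1B1.liver" = 1.1),
                 cl_met_other = 50, renal_filtration = FALSE)
  inh <- new("InhibitorExposure", name = "i", iu = 1,
             ki = c("OATP1B1" = 1, "OATP1B3" = 1), mbi = list(), kdeg = 0.03)
  base <- simulateDrug(d, ivBolus(1), ind, hvProf, t_end = 600, dt = 0.2)
  with_ <- simulateDrug(d, ivBolus(1), ind, hvProf, inhibitor = inh,
                        t_end = 600, dt = 0.2)
  aucr <- ncaSummary(with_@t, with_@conc$plasma, 1)$auc_0_inf /
    ncaSummary(base@t, base@conc$plasma, 1)$auc_0_inf
  expect_equal(aucr, 1 + 1 / 1, tolerance = 0.01)
})

test_that("muscle exposure is kp-proportional to plasma exposure", {
  ind <- refInd()
  d <- drugFixture("pitavastatin")
  sim <- simulateDrug(d, microdoseRegimen("pitavastatin"), ind, hvProf,
                      t_end = 400, dt = 0.2)
  auc_p <- ncaSummary(sim@t, sim@conc$plasma, 1)$auc_0_inf
  auc_m <- ncaSummary(sim@t, sim@conc$muscle, 1)$auc_0_inf
  expect_equal(auc_m / auc_p, d@kp_muscle, tolerance = 0.01)
  # kp = 0 leaves the muscle compartment untouched
  d0 <- degenerateIvDrug(1, 10, ind)
  s0 <- simulateDrug(d0, ivBolus(1), ind, hvProf)
  expect_true(all(s0@conc$muscle == 0))
})

test_that("statin muscle exposure rises in ESRD, more under repeated dosing", {
  sd_ <- muscleExposure(drugFixture("rosuvastatin"), hvPopulationSpec(),
                        esrdPopulationSpec(), hvProf, esrdProf, "SD",
                        n_trials = 1, n_per_trial = 6, seed = 8)
  md <- muscleExposure(drugFixture("rosuvastatin"), hvPopulationSpec(),
                       esrdPopulationSpec(), hvProf, esrdProf, "MD",
                       n_trials = 1, n_per_trial = 6, seed = 8)
  expect_gt(sd_$ratio, 1)
  expect_gte(md$ratio, sd_$ratio)
})

test_that("Morris mu* equals |coefficient| for additive linear models", {
  res <- morrisScreening(function(x) 2 * x[["a"]] - 3 * x[["b"]] + 0 * x[["c"]],
                         list(a = c(0, 1), b = c(0, 1), c = c(0, 1)),
                         r = 8, seed = 4)
  expect_equal(res$mu_star[res$parameter == "a"], 2, tolerance = 1e-10)
  expect_equal(res$mu_star[res$parameter == "b"], 3, tolerance = 1e-10)
  expect_equal(res$mu_star[res$parameter == "c"], 0, tolerance = 1e-10)
  expect_true(all(res$sigma < 1e-10))
  expect_equal(res$rank[res$parameter == "b"], 1L)
})

test_that("Morris detects interactions and is seed-reproducible", {
  f <- function(x) x[["a"]] * x[["b"]]
  r1 <- morrisScreening(f, list(a = c(0, 1), b = c(0, 1)), r = 10, seed = 9)
  r2 <- morrisScreening(f, list(a = c(0, 1), b = c(0, 1)), r = 10, seed = 9)
  expect_identical(r1, r2)
  expect_gt(r1$sigma[1], 0)
  expect_error(morrisScreening(f, list(a = c(0, Inf), b = c(0, 1)), r = 4),
               "finite")
})

test_that("PBPK factor screening ranks real knobs above structural no-ops", {
  res <- morrisPBPK(drugFixture("midazolam"), microdoseRegimen("midazolam"),
                    hvProf, r = 3, seed = 6, dt = 0.2)
  noop <- res$mu_star[res$parameter %in% c("cardiac_output_scalar",
                                           "liver_density")]
  expect_true(all(noop == 0))
  expect_gt(res$mu_star[res$parameter == "hsa"], 0)
  expect_gt(res$mu_star[res$parameter == "hematocrit"], 0)
})
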