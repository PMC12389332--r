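#' Exposure-ratio acceptance window
#'
#' Accepts when `lo <= pred/obs <= hi`, boundaries inclusive. The default
#' window 0.8-1.25 is the calibration acceptance criterion; (0.5, 2) is
#' the wider drug-model validation window.
#'
#' @param pred,obs positive exposure values (or ratios)
#' @param lo,hi window bounds
#' @return logical
#' @export
withinWindow <- function(pred, obs, lo = 0.8, hi = 1.25) {
  if (any(c(pred, obs) <= 0)) stop("pred and obs must be positive")
  if (lo >= hi) stop("window must be ordered")
  r <- pred / obs
  r >= lo & r <= hi
}

#' Predicted ESRD/HV exposure ratio
#'
#' Simulates matched virtual cohorts (common random numbers: the same seed
#' drives both population samplers, so demographic deviates are shared and
#' only the population specs and abundance profiles differ) and returns the
#' ratio of geometric-mean AUC in ESRD over healthy volunteers.
#'
#' @inheritParams populationSimulate
#' @param hv_spec,esrd_spec population specs
#' @param profile_hv,profile_esrd abundance profiles
#' @return AUCR (ESRD/HV), dimensionless
#' @export
predictAUCR <- function(drug, regimen, hv_spec, esrd_spec, profile_hv,
                        profile_esrd, n_trials = 2, n_per_trial = 10,
                        seed = 1, t_end = 72, dt = 0.05) {
  hv <- populationSimulate(drug, regimen, hv_spec, profile_hv,
                           n_trials = n_trials, n_per_trial = n_per_trial,
                           seed = seed, t_end = t_end, dt = dt)
  es <- populationSimulate(drug, regimen, esrd_spec, profile_esrd,
                           n_trials = n_trials, n_per_trial = n_per_trial,
                           seed = seed, t_end = t_end, dt = dt)
  unname(es$summary[["auc"]] / hv$summary[["auc"]])
}

#' Calibration context
#'
#' Bundles everything the back-calculation shares across steps: population
#' specs, the healthy-volunteer profile, the trial design and the seed.
#'
#' @param hv_spec,esrd_spec population specs
#' @param profile_hv healthy-volunteer [DMETProfile-class]
#' @param n_trials,n_per_trial matched-cohort design for the inversion
#' @param seed integer seed (common random numbers)
#' @param t_end,dt simulation window and grid
#' @return list used by [backcalcAbundance()] and [sequentialCalibration()]
#' @export
calibrationContext <- function(hv_spec = hvPopulationSpec(),
                               esrd_spec = esrdPopulationSpec(),
                               profile_hv = hvDmetProfile(),
                               n_trials = 2, n_per_trial = 10, seed = 1,
                               t_end = 72, dt = 0.05) {
  list(hv_spec = hv_spec, esrd_spec = esrd_spec, profile_hv = profile_hv,
       n_trials = n_trials, n_per_trial = n_per_trial, seed = seed,
       t_end = t_end, dt = dt)
}

.applyAssignments <- function(profile, assignments) {
  for (key in names(assignments)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    target <- parts[1]
    tissue <- if (length(parts) > 1) parts[2] else ""
    mode <- if (target == "BCRP" && tissue == "ileum") "abundance" else "activity"
    profile <- applyAbundanceMultiplier(profile, target, tissue,
                                        assignments[[key]], mode)
  }
  profile
}

#' Candidate ESRD profile from multiplier assignments
#'
#' Builds an ESRD profile from the healthy-volunteer profile by applying
#' named multipliers ("OATP1B", "P-gp.jejunum", "BCRP.ileum", "OAT3.renal",
#' "CYP3A4.liver", ...). BCRP ileum scales the relative abundance; all
#' other targets scale activity. OATP1B multipliers address the locked
#' OATP1B1/3 pair.
#'
#' @param profile_hv healthy-volunteer profile
#' @param assignments named numeric/list of multipliers
#' @return [DMETProfile-class] labelled "ESRD"
#' @export
candidateEsrdProfile <- function(profile_hv, assignments) {
  p <- .applyAssignments(profile_hv, assignments)
  p@label <- "ESRD"
  p
}

#' Back-calculate one abundance multiplier from an observed AUCR
#'
#' Root-finding inversion of the forward population model: finds the
#' multiplier m of the free (target, tissue) entry such that the predicted
#' ESRD/HV AUC ratio matches the observed one. Bisection on log(m) over
#' `bounds`; with matched seeds the forward model is deterministic, so the
#' inversion is too. Converges when |pred/obs - 1| <= `tol` or the bracket
#' width falls below `mtol` on the multiplier scale. The default `tol` is
#' deliberately sharp (1e-5) so that weakly identified pathways, whose
#' exposure ratio moves slowly with the multiplier, converge on the
#' bracket criterion — to the multiplier itself rather than to a loose
#' exposure match.
#'
#' @param drug,regimen victim drug and regimen
#' @param free_target multiplier key (e.g. "OATP1B", "BCRP.ileum")
#' @param observed_aucr observed ESRD/HV exposure ratio (> 0)
#' @param context a [calibrationContext()]
#' @param fixed named multipliers frozen from earlier steps
#' @param bounds search interval for the free multiplier
#' @param tol,mtol convergence tolerances (pred/obs and bracket width)
#' @param window acceptance window for the achieved pred/obs ratio
#' @return list: `multiplier`, `pred_obs` (achieved ratio), `accepted`,
#'   `iterations`, `aucr_pred`
#' @export
backcalcAbundance <- function(drug, regimen, free_target, observed_aucr,
                              context = calibrationContext(), fixed = list(),
                              bounds = c(0.01, 10), tol = 1e-5, mtol = 1e-4,
                              window = c(0.8, 1.25)) {
  if (observed_aucr <= 0) stop("observed_aucr must be positive")
  # the healthy-volunteer arm does not depend on the free multiplier:
  # simulate it once and re-evaluate only the ESRD arm per iteration
  hv_auc <- populationSimulate(drug, regimen, context$hv_spec,
                               context$profile_hv,
                               n_trials = context$n_trials,
                               n_per_trial = context$n_per_trial,
                               seed = context$seed, t_end = context$t_end,
                               dt = context$dt)$summary[["auc"]]
  f <- function(m) {
    asg <- fixed
    asg[[free_target]] <- m
    prof <- candidateEsrdProfile(context$profile_hv, asg)
    es <- populationSimulate(drug, regimen, context$esrd_spec, prof,
                             n_trials = context$n_trials,
                             n_per_trial = context$n_per_trial,
                             seed = context$seed, t_end = context$t_end,
                             dt = context$dt)
    unname(es$summary[["auc"]] / hv_auc)
  }
  lo <- log(bounds[1]); hi <- log(bounds[2])
  flo <- f(exp(lo)) - observed_aucr
  fhi <- f(exp(hi)) - observed_aucr
  if (sign(flo) == sign(fhi))
    stop(sprintf(paste0("observed AUCR %.4g outside the attainable range: ",
                        "f(%.3g) = %.4g, f(%.3g) = %.4g"),
                 observed_aucr, bounds[1], flo + observed_aucr,
                 bounds[2], fhi + observed_aucr))
  it <- 0L
  pred <- NA_real_
  repeat {
    it <- it + 1L
    mid <- (lo + hi) / 2
    pred <- f(exp(mid))
    if (abs(pred / observed_aucr - 1) <= tol) break
    if (sign(pred - observed_aucr) == sign(flo)) {
      lo <- mid; flo <- pred - observed_aucr
    } else hi <- mid
    if (exp(hi) - exp(lo) < mtol || it >= 60L) { mid <- (lo + hi) / 2; break }
  }
  m <- exp(mid)
  list(multiplier = m, pred_obs = pred / observed_aucr,
       accepted = withinWindow(pred, observed_aucr, window[1], window[2]),
       iterations = it, aucr_pred = pred)
}

#' Default sequential calibration protocol
#'
#' The probe order of the back-calculation: midazolam frees hepatic
#' CYP3A4; dabigatran frees jejunal P-gp; pitavastatin frees the locked
#' OATP1B1/3 pair; rosuvastatin frees ileal BCRP with OATP1B fixed from
#' the previous step and renal OAT3 scaled by the eGFR equation (0.246);
#' atorvastatin validates the combined profile without freeing anything.
#'
#' @return list of step definitions
#' @export
calibrationProtocol <- function() {
  list(
    list(drug = "midazolam", free = "CYP3A4.liver"),
    list(drug = "dabigatran", free = "P-gp.jejunum"),
    list(drug = "pitavastatin", free = "OATP1B"),
    list(drug = "rosuvastatin", free = "BCRP.ileum",
         extra_fixed = list("OAT3.renal" = 0.246)),
    list(drug = "atorvastatin", free = NA_character_))
}

#' Sequential back-calculation over the probe substrates
#'
#' Runs the calibration protocol against observed ESRD/HV exposure ratios:
#' each step estimates one multiplier by [backcalcAbundance()] and freezes
#' it for subsequent steps; the final step predicts the validation probe's
#' AUCR under the fully assembled profile and checks it against the
#' acceptance window without freeing any parameter.
#'
#' @param observations named numeric: drug name -> observed AUCR. Drugs are
#'   matched to protocol steps by name.
#' @param context a [calibrationContext()]
#' @param protocol list of steps (see [calibrationProtocol()])
#' @param regimens function(name) returning the [DoseRegimen-class] per
#'   drug (default microdose cocktail)
#' @param drugs function(name) returning the [DrugModel-class] per drug
#' @param window acceptance window
#' @param bounds,tol,mtol passed to [backcalcAbundance()]
#' @return list: `steps` data.frame (drug, free target, estimate,
#'   achieved pred/obs, accepted), `multipliers` (named list),
#'   `profile_esrd` (final [DMETProfile-class])
#' @export
sequentialCalibration <- function(observations, context = calibrationContext(),
                                  protocol = calibrationProtocol(),
                                  regimens = microdoseRegimen,
                                  drugs = drugFixture, window = c(0.8, 1.25),
                                  bounds = c(0.01, 10), tol = 1e-5,
                                  mtol = 1e-4) {
  fixed <- list()
  rows <- list()
  for (step in protocol) {
    if (!step$drug %in% names(observations))
      stop(sprintf("no observed AUCR for protocol drug '%s'", step$drug))
    obs <- observations[[step$drug]]
    drug <- drugs(step$drug)
    regimen <- regimens(step$drug)
    if (!is.null(step$extra_fixed)) fixed[names(step$extra_fixed)] <- step$extra_fixed
    if (is.na(step$free)) {
      prof <- candidateEsrdProfile(context$profile_hv, fixed)
      pred <- predictAUCR(drug, regimen, context$hv_spec, context$esrd_spec,
                          context$profile_hv, prof,
                          n_trials = context$n_trials,
                          n_per_trial = context$n_per_trial,
                          seed = context$seed, t_end = context$t_end,
                          dt = context$dt)
      rows[[length(rows) + 1]] <- data.frame(
        drug = step$drug, free_target = NA_character_,
        multiplier = NA_real_, pred_obs = pred / obs,
        accepted = withinWindow(pred, obs, window[1], window[2]))
    } else {
      est <- tryCatch(
        backcalcAbundance(drug, regimen, step$free, obs, context,
                          fixed = fixed, bounds = bounds, tol = tol,
                          mtol = mtol, window = window),
        error = function(e) stop(sprintf("calibration step '%s' failed: %s",
                                         step$drug, conditionMessage(e))))
      fixed[[step$free]] <- est$multiplier
      rows[[length(rows) + 1]] <- data.frame(
        drug = step$drug, free_target = step$free,
        multiplier = est$multiplier, pred_obs = est$pred_obs,
        accepted = est$accepted)
    }
  }
  list(steps = do.call(rbind, rows), multipliers = fixed,
       profile_esrd = candidateEsrdProfile(context$profile_hv, fixed))
}

#' Observed-like AUCRs from a ground-truth profile
#'
#' Forward-simulates the ESRD/HV exposure ratio of each protocol drug under
#' a given ESRD profile — the synthetic stand-in for the clinical observed
#' ratios, used for self-consistency recovery of the calibration.
#'
#' @param profile_esrd ground-truth ESRD profile
#' @param context a [calibrationContext()]
#' @param drugs,regimens fixture accessors
#' @param names_ drug names to simulate
#' @return named numeric of AUCRs
#' @export
syntheticObservedAUCR <- function(profile_esrd, context = calibrationContext(),
                                  drugs = drugFixture,
                                  regimens = microdoseRegimen,
                                  names_ = c("midazolam", "dabigatran",
                                             "pitavastatin", "rosuvastatin",
                                             "atorvastatin")) {
  vapply(setNames(names_, names_), function(nm)
    predictAUCR(drugs(nm), regimens(nm), context$hv_spec, context$esrd_spec,
                context$profile_hv, profile_esrd,
                n_trials = context$n_trials,
                n_per_trial = context$n_per_trial, seed = context$seed,
                t_end = context$t_end, dt = context$dt),
    numeric(1))
}
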