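#' Drug-drug(-disease) interaction scenario
#'
#' Simulates a victim drug with and without a perpetrator on matched
#' virtual cohorts (identical seed, hence identical subjects) and returns
#' geometric-mean exposure ratios with/without perpetrator.
#'
#' @inheritParams populationSimulate
#' @param victim victim [DrugModel-class]
#' @param perpetrator an [InhibitorExposure-class]
#' @return one-row data.frame: victim, perpetrator, population,
#'   aucr_w_wo, cmaxr_w_wo
#' @export
ddiScenario <- function(victim, perpetrator, regimen, spec, profile,
                        n_trials = 10, n_per_trial = 10, seed = 1,
                        t_end = 72, dt = 0.05) {
  without <- populationSimulate(victim, regimen, spec, profile,
                                n_trials = n_trials, n_per_trial = n_per_trial,
                                seed = seed, t_end = t_end, dt = dt)
  with_ <- populationSimulate(victim, regimen, spec, profile,
                              n_trials = n_trials, n_per_trial = n_per_trial,
                              seed = seed, inhibitor = perpetrator,
                              t_end = t_end, dt = dt)
  data.frame(victim = victim@name, perpetrator = perpetrator@name,
             population = spec@label,
             aucr_w_wo = unname(with_$summary[["auc"]] / without$summary[["auc"]]),
             cmaxr_w_wo = unname(with_$summary[["cmax"]] / without$summary[["cmax"]]))
}

#' Muscle exposure in ESRD versus healthy volunteers
#'
#' Simulates muscle AUC of a victim (statin) in both populations under a
#' single dose (AUC over 0-72 h) or a multiple-dose regimen (AUC over the
#' last dosing interval, approximating steady state), on matched cohorts.
#'
#' @inheritParams populationSimulate
#' @param victim victim [DrugModel-class] with a muscle partition
#'   coefficient
#' @param spec_hv,spec_esrd population specs
#' @param profile_hv,profile_esrd abundance profiles
#' @param regimen_type "SD" (single dose) or "MD" (multiple dose)
#' @param amount dose per administration, mg
#' @param n_doses,interval multiple-dose design
#' @return one-row data.frame: victim, regimen, muscle_auc_hv,
#'   muscle_auc_esrd, ratio (ESRD/HV)
#' @export
muscleExposure <- function(victim, spec_hv, spec_esrd, profile_hv,
                           profile_esrd, regimen_type = c("SD", "MD"),
                           amount = 10, n_doses = 7, interval = 24,
                           n_trials = 2, n_per_trial = 10, seed = 1,
                           dt = 0.05) {
  regimen_type <- match.arg(regimen_type)
  if (victim@kp_muscle < 0) stop("victim must have a muscle partition coefficient")
  if (regimen_type == "SD") {
    regimen <- doseRegimen("oral", amount)
    t_end <- 72
    window <- c(0, 72)
  } else {
    regimen <- doseRegimen("oral", amount, n_doses = n_doses, interval = interval)
    t_end <- interval * n_doses
    window <- c(interval * (n_doses - 1), interval * n_doses)
  }
  muscleAuc <- function(spec, profile) {
    sims <- populationSimulateRaw(victim, regimen, spec, profile,
                                  n_trials = n_trials,
                                  n_per_trial = n_per_trial, seed = seed,
                                  t_end = t_end, dt = dt)
    aucs <- vapply(sims, function(sim) {
      keep <- sim@t >= window[1] & sim@t <= window[2]
      aucLinUpLogDown(sim@t[keep], sim@conc$muscle[keep])
    }, numeric(1))
    exp(mean(log(pmax(aucs, .Machine$double.xmin))))
  }
  hv <- muscleAuc(spec_hv, profile_hv)
  es <- muscleAuc(spec_esrd, profile_esrd)
  data.frame(victim = victim@name, regimen = regimen_type,
             muscle_auc_hv = hv, muscle_auc_esrd = es, ratio = es / hv)
}

# Per-subject SimulationResult list (no summarising); shares the sampling
# scheme of populationSimulate.
populationSimulateRaw <- function(drug, regimen, spec, profile, n_trials,
                                  n_per_trial, seed, inhibitor = NULL,
                                  t_end = 72, dt = 0.05) {
  sims <- list()
  for (tr in seq_len(n_trials)) {
    cohort <- sampleCohort(spec, n_per_trial, seed = seed + tr)
    for (ind in cohort)
      sims[[length(sims) + 1]] <- simulateDrug(drug, regimen, ind, profile,
                                               inhibitor, t_end = t_end,
                                               dt = dt)
  }
  sims
}

#' Morris elementary-effects screening
#'
#' Trajectory (one-at-a-time) Morris design on a p-level grid: r
#' trajectories, each perturbing every parameter once by Delta =
#' p / (2(p - 1)) on the unit cube, scaled to the supplied ranges.
#' Reports mu* (mean absolute elementary effect), sigma (standard
#' deviation of the effects) and the mu* ranking.
#'
#' @param model function(named numeric vector) -> scalar output
#' @param ranges named list parameter -> c(lo, hi), finite
#' @param r number of trajectories (>= 2)
#' @param levels number of grid levels p (default 4)
#' @param seed integer seed
#' @return data.frame: parameter, mu_star, sigma, rank; attribute
#'   `trajectories` = r
#' @export
morrisScreening <- function(model, ranges, r = 20, levels = 4, seed = 1) {
  stopifnot(r >= 2, levels >= 2)
  k <- length(ranges)
  pars <- names(ranges)
  if (is.null(pars) || any(!nzchar(pars))) stop("ranges must be named")
  rng <- do.call(rbind, ranges)
  if (any(!is.finite(rng))) stop("ranges must be finite")
  delta <- levels / (2 * (levels - 1))
  base_levels <- seq(0, 1 - delta, length.out = levels / 2)
  ee <- matrix(NA_real_, nrow = r, ncol = k, dimnames = list(NULL, pars))
  withSeed(seed, {
    for (tr in seq_len(r)) {
      x <- base_levels[sample.int(length(base_levels), k, replace = TRUE)]
      direction <- sample(c(-1, 1), k, replace = TRUE)
      # keep the perturbed point inside [0, 1]
      direction[x + direction * delta > 1] <- -1
      direction[x + direction * delta < 0] <- 1
      order_ <- sample.int(k)
      scale_x <- function(u) setNames(rng[, 1] + u * (rng[, 2] - rng[, 1]), pars)
      f0 <- model(scale_x(x))
      for (j in order_) {
        x2 <- x
        x2[j] <- x[j] + direction[j] * delta
        f1 <- model(scale_x(x2))
        ee[tr, j] <- (f1 - f0) / (direction[j] * delta)
        x <- x2
        f0 <- f1
      }
    }
  })
  res <- data.frame(parameter = pars,
                    mu_star = apply(abs(ee), 2, mean),
                    sigma = apply(ee, 2, sd))
  res$rank <- rank(-res$mu_star, ties.method = "min")
  rownames(res) <- NULL
  attr(res, "trajectories") <- r
  res
}

#' Morris screening of the PBPK physiological factors
#'
#' Screens the sensitivity of a drug's simulated plasma AUC(0-t) to the
#' physiological factors of the population model: serum albumin,
#' hematocrit, alpha-1-acid glycoprotein, kidney volume and density,
#' gastric residence time and colon drug mean residence time, plus the
#' cardiac-output scalar and liver density. The last two are carried for
#' completeness but do not enter the reduced model, so their mu* is
#' structurally zero.
#'
#' @param drug a [DrugModel-class]
#' @param regimen a [DoseRegimen-class]
#' @param profile a [DMETProfile-class]
#' @param individual baseline [VirtualIndividual-class] to perturb
#' @param r,levels,seed Morris design
#' @param span multiplicative half-width of each factor range around its
#'   baseline (default 0.5: range = baseline x (1 +/- 0.5))
#' @param t_end,dt simulation window
#' @return data.frame as [morrisScreening()]
#' @export
morrisPBPK <- function(drug, regimen, profile,
                       individual = referenceIndividual(), r = 10,
                       levels = 4, seed = 1, span = 0.5, t_end = 72,
                       dt = 0.1) {
  base <- c(hsa = individual@hsa, hematocrit = individual@hematocrit,
            agp = individual@agp, kidney_volume = individual@kidney_volume,
            kidney_density = individual@kidney_density,
            gastric_rt = individual@gi[["gastric"]],
            colon_mrt = individual@gi[["colon_mrt"]],
            cardiac_output_scalar = 1, liver_density = 1)
  ranges <- lapply(base, function(v) c(v * (1 - span), v * (1 + span)))
  kv0 <- individual@kidney_volume * individual@kidney_density
  model <- function(x) {
    ind <- individual
    ind@hsa <- x[["hsa"]]
    ind@hematocrit <- min(x[["hematocrit"]], 0.65)
    ind@agp <- x[["agp"]]
    ind@renal_scale <- individual@renal_scale *
      (x[["kidney_volume"]] * x[["kidney_density"]]) / kv0
    ind@gi[["gastric"]] <- x[["gastric_rt"]]
    ind@gi[["colon_mrt"]] <- x[["colon_mrt"]]
    sim <- simulateDrug(drug, regimen, ind, profile, t_end = t_end, dt = dt)
    aucLinUpLogDown(sim@t, sim@conc$plasma)
  }
  morrisScreening(model, ranges, r = r, levels = levels, seed = seed)
}
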