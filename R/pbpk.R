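#' Physiological scaling constants of the reduced PBPK model
#'
#' Fixed constants converting intrinsic clearances and abundances into
#' whole-organ clearances, plus reference flows and volumes. These are
#' representative adult values (liver microsomal protein 40 mg/g, liver
#' 1560 g, reference body weight 70 kg); the transporter scalars lump cell
#' number and unit conversion into one documented constant per tissue.
#'
#' @return named list of constants
#' @export
pbpkScales <- function() {
  list(
    liver_enzyme   = 40 * 1560 * 6e-5, # (uL/min/mg protein) -> L/h whole liver
    liver_transporter = 100,           # (uL/min/10^6 cells x AA) -> L/h whole liver
    gut_enzyme     = 0.06,             # (uL/min/pmol x nmol segment) -> L/h
    gut_transporter = 1,               # (uL/min/10^6 x AA) -> L/h segment
    renal_transporter = 0.30,          # (uL/min/10^6 x AA) -> L/h kidney
    jejunum_fraction = 0.7,            # share of intestinal CYP3A4 in jejunum
    q_hepatic_blood = 97,              # L/h at 70 kg
    q_muscle_blood  = 33,              # L/h at 70 kg
    v_liver_ec = 0.6, v_liver_ic = 1.0, v_enterocyte = 0.3, # L
    k_basolateral = 15,                # 1/h enterocyte basolateral exit
    t_jejunum = 1.75, t_ileum = 1.57,  # h small-intestinal residence
    gfr_reference = 120,               # mL/min/1.73m^2 healthy reference
    muscle_volume_frac = 0.4           # L/kg body weight
  )
}

.clintKey <- function(drug, key) {
  v <- drug@clint[[key]]
  if (is.null(v)) 0 else v
}

.pathClint <- function(drug, target, tissue, profile, individual, inhibitor) {
  key <- paste0(target, ".", tissue)
  if (is.null(drug@clint[[key]])) return(0)
  effectiveClint(drug, target, tissue, profile, individual, inhibitor)
}

#' Individual unbound plasma fraction
#'
#' The population-typical fu (healthy value, times the measured ESRD/HV
#' ratio when the profile describes ESRD) is scaled to the individual's
#' binding-protein level: `fu = 1 / (1 + (1 - fu_pop)/fu_pop * P/P_ref)`,
#' where P is the individual's HSA or AGP level and P_ref the population
#' mean. Drugs with `binding_protein = "none"` use the population fu.
#'
#' @param drug a [DrugModel-class]
#' @param individual a [VirtualIndividual-class]
#' @param esrd logical; apply the ESRD fu ratio
#' @return unbound fraction in (0, 1]
#' @export
individualFu <- function(drug, individual, esrd = FALSE) {
  fu_pop <- drug@fu_hv * if (esrd) drug@fu_esrd_ratio else 1
  fu_pop <- min(fu_pop, 1)
  if (drug@binding_protein == "none" || fu_pop >= 1) return(fu_pop)
  prel <- switch(drug@binding_protein,
                 HSA = individual@hsa / individual@hsa_ref,
                 AGP = individual@agp / individual@agp_ref)
  1 / (1 + (1 - fu_pop) / fu_pop * prel)
}

#' Assemble the ODE parameter vector for one subject
#'
#' Translates a drug model, an individual and an abundance profile (plus an
#' optional perpetrator) into the 32-element parameter vector consumed by
#' the compiled model. All abundance/activity/inhibition scaling runs
#' through [effectiveClint()]; unbound-fraction and flow scaling are
#' individualised here.
#'
#' @inheritParams individualFu
#' @param profile a [DMETProfile-class]; `profile@label == "ESRD"` switches
#'   on the ESRD fu ratio
#' @param inhibitor optional [InhibitorExposure-class]
#' @return named numeric vector of length 32
#' @export
buildPbpkParams <- function(drug, individual, profile, inhibitor = NULL) {
  s <- pbpkScales()
  esrd <- profile@label == "ESRD"
  fu <- individualFu(drug, individual, esrd)
  bwscale <- (individual@bw / 70)^0.75
  plasma <- 1 - individual@hematocrit

  gut_cyp <- .pathClint(drug, "CYP3A4", "intestine", profile, individual, inhibitor)
  clmet_j <- gut_cyp * s$jejunum_fraction * s$gut_enzyme
  clmet_i <- gut_cyp * (1 - s$jejunum_fraction) * s$gut_enzyme
  clmet_c <- .pathClint(drug, "CYP3A4", "colon", profile, individual, inhibitor) * s$gut_enzyme
  cleff_j <- .pathClint(drug, "P-gp", "jejunum", profile, individual, inhibitor) * s$gut_transporter
  cleff_i <- .pathClint(drug, "BCRP", "ileum", profile, individual, inhibitor) * s$gut_transporter

  cl_upt <- (.pathClint(drug, "OATP1B1", "liver", profile, individual, inhibitor) +
             .pathClint(drug, "OATP1B3", "liver", profile, individual, inhibitor)) *
    s$liver_transporter
  clmet_h <- .pathClint(drug, "CYP3A4", "liver", profile, individual, inhibitor) *
    s$liver_enzyme + drug@cl_met_other
  cl_bil <- (.pathClint(drug, "P-gp", "liver", profile, individual, inhibitor) +
             .pathClint(drug, "BCRP", "liver", profile, individual, inhibitor)) *
    s$liver_transporter
  has_liver <- as.numeric(drug@ps_liver > 0 || cl_upt > 0 || clmet_h > 0 || cl_bil > 0)

  cl_sec <- (.pathClint(drug, "OAT3", "renal", profile, individual, inhibitor) +
             .pathClint(drug, "BCRP", "renal", profile, individual, inhibitor)) *
    s$renal_transporter * individual@renal_scale * fu
  cl_filt <- if (drug@renal_filtration) fu * individual@egfr * 0.06 else 0

  c(k_ge = 1 / individual@gi[["gastric"]],
    k_jt = 1 / s$t_jejunum, k_it = 1 / s$t_ileum,
    k_ct = 1 / individual@gi[["colon_mrt"]],
    ka_j = drug@ka, ka_i = drug@ka, ka_c = drug@ka * drug@colon_ka_factor,
    k_bas = s$k_basolateral, V_ent = s$v_enterocyte,
    CLeff_j = cleff_j, CLeff_i = cleff_i, CLeff_c = 0,
    CLmet_j = clmet_j, CLmet_i = clmet_i, CLmet_c = clmet_c,
    k_conv = drug@prodrug_conversion_k,
    Q_h = s$q_hepatic_blood * plasma * bwscale,
    V_ec = s$v_liver_ec, V_ic = s$v_liver_ic,
    PS = drug@ps_liver, CL_upt = cl_upt, CLmet_h = clmet_h, CL_bil = cl_bil,
    fu = fu, Vc = drug@vss * individual@bw,
    Q_m = s$q_muscle_blood * plasma * bwscale,
    Vm = s$muscle_volume_frac * individual@bw, kp = drug@kp_muscle,
    CL_filt = cl_filt, CL_sec = cl_sec, cl_extra = drug@cl_extra,
    has_liver = has_liver)
}

.stateNames <- c("stomach", "jejunum_lumen", "ileum_lumen", "colon_lumen",
                 "jejunum_ent", "ileum_ent", "colon_ent", "prodrug_pool",
                 "liver_ec", "liver_ic", "central", "muscle",
                 "elim_gut_metabolism", "elim_hepatic_metabolism",
                 "elim_biliary", "elim_renal_filtration",
                 "elim_renal_secretion", "elim_systemic", "elim_fecal")

# Reference R implementation of the compiled right-hand side; used to
# cross-check the C model and available via simulateDrug(engine = "R").
pbpkDerivsR <- function(t, y, p) {
  Cp <- y[11] / p[["Vc"]]
  Fabs <- p[["k_bas"]] * (y[5] + y[6] + y[7])
  formed <- p[["k_conv"]] * y[8]
  d <- numeric(19)
  d[1] <- -p[["k_ge"]] * y[1]
  d[2] <- p[["k_ge"]] * y[1] - (p[["k_jt"]] + p[["ka_j"]]) * y[2] + p[["CLeff_j"]] / p[["V_ent"]] * y[5]
  d[3] <- p[["k_jt"]] * y[2] - (p[["k_it"]] + p[["ka_i"]]) * y[3] + p[["CLeff_i"]] / p[["V_ent"]] * y[6]
  d[4] <- p[["k_it"]] * y[3] - (p[["k_ct"]] + p[["ka_c"]]) * y[4] + p[["CLeff_c"]] / p[["V_ent"]] * y[7]
  d[19] <- p[["k_ct"]] * y[4]
  d[5] <- p[["ka_j"]] * y[2] - (p[["k_bas"]] + (p[["CLeff_j"]] + p[["CLmet_j"]]) / p[["V_ent"]]) * y[5]
  d[6] <- p[["ka_i"]] * y[3] - (p[["k_bas"]] + (p[["CLeff_i"]] + p[["CLmet_i"]]) / p[["V_ent"]]) * y[6]
  d[7] <- p[["ka_c"]] * y[4] - (p[["k_bas"]] + (p[["CLeff_c"]] + p[["CLmet_c"]]) / p[["V_ent"]]) * y[7]
  d[13] <- (p[["CLmet_j"]] * y[5] + p[["CLmet_i"]] * y[6] + p[["CLmet_c"]] * y[7]) / p[["V_ent"]]
  if (p[["k_conv"]] > 0) d[8] <- Fabs - formed
  Jh <- 0
  if (p[["has_liver"]] > 0.5) {
    Cec <- y[9] / p[["V_ec"]]; Cic <- y[10] / p[["V_ic"]]
    influx <- (p[["PS"]] + p[["CL_upt"]]) * p[["fu"]] * Cec
    back <- p[["PS"]] * Cic
    Jh <- p[["Q_h"]] * (Cp - Cec)
    d[9] <- Jh - influx + back + if (p[["k_conv"]] > 0) 0 else Fabs
    d[10] <- influx - back - (p[["CLmet_h"]] + p[["CL_bil"]]) * Cic
    d[14] <- p[["CLmet_h"]] * Cic
    d[15] <- p[["CL_bil"]] * Cic
  }
  Jm <- if (p[["kp"]] > 0) p[["Q_m"]] * (Cp - y[12] / (p[["Vm"]] * p[["kp"]])) else 0
  d[12] <- Jm
  d[11] <- -Jh - Jm - (p[["CL_filt"]] + p[["CL_sec"]] + p[["cl_extra"]]) * Cp +
    if (p[["k_conv"]] > 0) formed else if (p[["has_liver"]] <= 0.5) Fabs else 0
  d[16] <- p[["CL_filt"]] * Cp
  d[17] <- p[["CL_sec"]] * Cp
  d[18] <- p[["cl_extra"]] * Cp
  list(d)
}

#' Simulate one subject
#'
#' Integrates the reduced PBPK system for one individual under a dose
#' regimen: gastric emptying, segmental intestinal transit with enterocyte
#' uptake, apical efflux (P-gp in jejunum, BCRP in ileum) and gut CYP3A4
#' loss; optional permeability-limited liver with OATP1B uptake, CYP3A4
#' metabolism and biliary efflux; systemic circulation with a
#' perfusion-limited muscle compartment; renal elimination by unbound
#' glomerular filtration plus OAT3/BCRP-mediated secretion; optional
#' first-order prodrug conversion, in which case the plasma readout is the
#' active moiety.
#'
#' @param drug a [DrugModel-class]
#' @param regimen a [DoseRegimen-class]
#' @param individual a [VirtualIndividual-class]
#' @param profile a [DMETProfile-class]
#' @param inhibitor optional [InhibitorExposure-class] (static unbound
#'   exposure)
#' @param t_end end of simulation, h (must exceed the last dose time)
#' @param dt output grid step, h
#' @param engine "C" (compiled, default) or "R" (reference implementation)
#' @param rtol,atol solver tolerances
#' @return a [SimulationResult-class]
#' @export
simulateDrug <- function(drug, regimen, individual, profile, inhibitor = NULL,
                         t_end = 72, dt = 0.05, engine = c("C", "R"),
                         rtol = 1e-8, atol = 1e-10) {
  engine <- match.arg(engine)
  validObject(drug); validObject(regimen)
  if (t_end <= max(regimen@times)) stop("t_end must exceed the last dose time")
  p <- buildPbpkParams(drug, individual, profile, inhibitor)
  y0 <- setNames(numeric(19), .stateNames)
  times <- seq(0, t_end, by = dt)
  dose_state <- if (regimen@route == "oral") 1L else 11L
  # dose at t = 0 enters the initial condition; later doses are solver events
  y0[dose_state] <- regimen@amount * sum(regimen@times == 0)
  later <- regimen@times[regimen@times > 0]
  ev <- if (length(later))
    list(data = data.frame(var = dose_state, time = later,
                           value = regimen@amount, method = "add"))
  else NULL
  times <- sort(unique(c(times, regimen@times)))
  if (engine == "C") {
    out <- deSolve::lsoda(y0, times, func = "pbpk_derivs", parms = unname(p),
                          dllname = "esrdpbpk", initfunc = "pbpk_initmod",
                          events = ev, rtol = rtol, atol = atol,
                          maxsteps = 50000)
  } else {
    if (!is.null(ev)) ev$data$var <- .stateNames[dose_state]
    out <- deSolve::lsoda(y0, times, func = function(t, y, parms) pbpkDerivsR(t, y, parms),
                          parms = p, events = ev,
                          rtol = rtol, atol = atol, maxsteps = 50000)
  }
  if (attr(out, "istate")[1] < 0) stop("ODE integration failed to converge")
  out <- as.data.frame(out)
  names(out) <- c("time", .stateNames)
  if (any(out[-1] < -1e-6)) stop("negative state encountered in simulation")
  vm <- p[["Vm"]]
  elim_cols <- grep("^elim_", .stateNames, value = TRUE)
  res_cols <- setdiff(.stateNames, elim_cols)
  new("SimulationResult",
      t = out$time,
      conc = list(plasma = pmax(out$central, 0) / p[["Vc"]],
                  muscle = if (drug@kp_muscle > 0) pmax(out$muscle, 0) / vm else rep(0, nrow(out))),
      eliminated = as.matrix(out[elim_cols]),
      residual = as.matrix(out[res_cols]),
      dose_total = regimen@amount * length(regimen@times))
}

#' Audit mass balance of a simulation
#'
#' @param result a [SimulationResult-class]
#' @param regimen the [DoseRegimen-class] used
#' @return maximum absolute relative mass-balance error over the output
#'   grid (relative to total administered dose)
#' @export
massBalanceError <- function(result, regimen) {
  administered <- vapply(result@t, function(tt)
    regimen@amount * sum(regimen@times <= tt), numeric(1))
  total <- rowSums(result@residual) + rowSums(result@eliminated)
  # at an exact later dose time the reported state may precede the event;
  # accept either accounting there
  err <- pmin(abs(total - administered),
              abs(total - administered +
                    regimen@amount * (result@t %in% regimen@times[regimen@times > 0])))
  max(err) / (regimen@amount * length(regimen@times))
}

#' Population simulation
#'
#' Samples `n_trials` trials of `n_per_trial` virtual subjects, simulates
#' each, and summarises exposure (AUC over the output window by the
#' linear-up/log-down rule, Cmax, muscle AUC) per trial and pooled as
#' geometric means.
#'
#' @inheritParams simulateDrug
#' @param spec a [PopulationSpec-class]
#' @param n_trials,n_per_trial trial design (default 10 x 10, half female,
#'   ages 20-70)
#' @param seed integer master seed; trial `i` uses `seed + i`
#' @return list with `subjects` (per-subject data.frame), `trials`
#'   (per-trial geometric means) and `summary` (pooled geometric means)
#' @export
populationSimulate <- function(drug, regimen, spec, profile, n_trials = 10,
                               n_per_trial = 10, seed = 1, inhibitor = NULL,
                               t_end = 72, dt = 0.05) {
  stopifnot(n_trials >= 1, n_per_trial >= 1)
  rows <- list()
  for (tr in seq_len(n_trials)) {
    cohort <- sampleCohort(spec, n_per_trial, seed = seed + tr)
    for (i in seq_along(cohort)) {
      sim <- tryCatch(
        simulateDrug(drug, regimen, cohort[[i]], profile, inhibitor,
                     t_end = t_end, dt = dt),
        error = function(e) stop(sprintf("trial %d subject %d: %s", tr, i,
                                         conditionMessage(e))))
      rows[[length(rows) + 1]] <- data.frame(
        trial = tr, subject = i,
        auc = aucLinUpLogDown(sim@t, sim@conc$plasma),
        cmax = max(sim@conc$plasma),
        tmax = sim@t[which.max(sim@conc$plasma)],
        auc_muscle = aucLinUpLogDown(sim@t, sim@conc$muscle))
    }
  }
  subjects <- do.call(rbind, rows)
  geomean <- function(x) exp(mean(log(pmax(x, .Machine$double.xmin))))
  trials <- do.call(rbind, lapply(split(subjects, subjects$trial), function(d)
    data.frame(trial = d$trial[1], auc = geomean(d$auc), cmax = geomean(d$cmax),
               auc_muscle = geomean(d$auc_muscle))))
  rownames(trials) <- NULL
  list(subjects = subjects, trials = trials,
       summary = c(auc = geomean(subjects$auc), cmax = geomean(subjects$cmax),
                   auc_muscle = geomean(subjects$auc_muscle)))
}
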