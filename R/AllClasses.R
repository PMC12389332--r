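#' @import methods
#' @importFrom stats coef cor.test lm median na.omit quantile rbinom rlnorm
#'   rnorm runif sd setNames var predict
NULL

setClassUnion("listOrNULL", c("list", "NULL"))

#' Sex-stratified demographic model
#'
#' Height is a quadratic polynomial in age (cm vs years); weight is a
#' log-linear model in height (kg vs cm), both stratified by sex. The
#' coefficient layout matches the CK-NET demographic equations used for the
#' Chinese ESRD population.
#'
#' @slot height named list with elements `M` and `F`, each `c(c0, c1, c2)`
#' @slot weight named list with elements `M` and `F`, each `c(a0, a1)`
#' @export
setClass("DemographicModel", representation(height = "list", weight = "list"))

setValidity("DemographicModel", function(object) {
  msg <- character()
  for (s in c("M", "F")) {
    h <- object@height[[s]]; w <- object@weight[[s]]
    if (is.null(h) || length(h) != 3) msg <- c(msg, sprintf("height[[%s]] must have 3 coefficients", s))
    if (is.null(w) || length(w) != 2) msg <- c(msg, sprintf("weight[[%s]] must have 2 coefficients", s))
  }
  if (length(msg)) msg else TRUE
})

#' Virtual population specification
#'
#' Everything needed to sample virtual individuals of one population
#' (healthy volunteers or ESRD patients): demographic models, serum
#' creatinine strata, blood chemistry, kidney size, gastrointestinal
#' residence times and phenotype frequencies.
#'
#' @slot label `"HV"` or `"ESRD"`
#' @slot demographics a [DemographicModel-class]
#' @slot creatinine data.frame with columns sex, lo, hi (age band, years),
#'   mean (umol/L), cv (percent)
#' @slot blood data.frame with columns sex, hct_mean (percent), hct_cv,
#'   agp_mean (g/L), agp_cv, hsa_mean (g/L), hsa_cv
#' @slot kidney named numeric: baseline (mL), bw_coeff (mL/kg),
#'   bh_coeff (mL/m), cv (percent), density (g/L)
#' @slot gi named numeric: gastric_fasted, gastric_fed, colon_residence,
#'   colon_mrt_male, colon_mrt_female (hours)
#' @slot phenotype_freq named list: target -> named probability vector over
#'   phenotypes (EM/T, PM/T, IM/T, UM/T)
#' @slot age_range numeric length 2 (years), trial sampling range
#' @slot female_fraction fraction of females in trial sampling
#' @slot height_cv,weight_cv lognormal inter-individual CV (percent) added
#'   around the demographic polynomials
#' @export
setClass("PopulationSpec", representation(
  label = "character", demographics = "DemographicModel",
  creatinine = "data.frame", blood = "data.frame", kidney = "numeric",
  gi = "numeric", phenotype_freq = "list", age_range = "numeric",
  female_fraction = "numeric", height_cv = "numeric", weight_cv = "numeric"))

setValidity("PopulationSpec", function(object) {
  msg <- character()
  if (!object@label %in% c("HV", "ESRD")) msg <- c(msg, "label must be HV or ESRD")
  if (any(object@creatinine$mean <= 0) || any(object@creatinine$cv <= 0))
    msg <- c(msg, "creatinine stratum means and CVs must be positive")
  for (s in c("M", "F")) {
    b <- object@creatinine[object@creatinine$sex == s, , drop = FALSE]
    b <- b[order(b$lo), , drop = FALSE]
    if (nrow(b) == 0) { msg <- c(msg, sprintf("no creatinine strata for sex %s", s)); next }
    if (b$lo[1] > 18 || !is.infinite(b$hi[nrow(b)]))
      msg <- c(msg, sprintf("creatinine strata for %s must cover [18, Inf)", s))
    if (nrow(b) > 1 && any(abs(b$hi[-nrow(b)] - b$lo[-1]) > 1e-9))
      msg <- c(msg, sprintf("creatinine strata for %s must be contiguous and disjoint", s))
  }
  bl <- object@blood
  if (any(bl$hct_mean <= 10 | bl$hct_mean >= 60))
    msg <- c(msg, "hematocrit mean must lie in (10, 60) percent")
  if (any(c(bl$agp_mean, bl$hsa_mean) <= 0)) msg <- c(msg, "protein means must be positive")
  if (object@kidney[["density"]] <= 0) msg <- c(msg, "kidney density must be positive")
  if (any(object@gi <= 0)) msg <- c(msg, "GI residence times must be positive")
  for (tg in names(object@phenotype_freq)) {
    p <- object@phenotype_freq[[tg]]
    if (abs(sum(p) - 1) > 1e-8) msg <- c(msg, sprintf("phenotype frequencies for %s must sum to 1", tg))
  }
  if (object@female_fraction < 0 || object@female_fraction > 1)
    msg <- c(msg, "female_fraction must lie in [0, 1]")
  if (length(object@age_range) != 2 || diff(object@age_range) < 0)
    msg <- c(msg, "age_range must be an ordered pair")
  if (length(msg)) msg else TRUE
})

#' A sampled virtual individual
#'
#' One realisation of the population model: demographics, serum creatinine,
#' eGFR (CKD-EPI 2009), blood chemistry, kidney volume, GI residence times,
#' phenotypes per enzyme/transporter target, and the fractional renal OAT3
#' secretory function (1 in healthy volunteers, eGFR-scaled in ESRD).
#'
#' @slot sex "M" or "F"
#' @slot age years
#' @slot bh body height, cm
#' @slot bw body weight, kg
#' @slot scr serum creatinine, umol/L
#' @slot egfr mL/min/1.73 m^2 (CKD-EPI 2009, no race coefficient)
#' @slot hematocrit fraction (0-1)
#' @slot hsa,agp g/L
#' @slot hsa_ref,agp_ref population mean binding-protein levels (g/L), used
#'   to scale the unbound fraction per individual
#' @slot kidney_volume mL
#' @slot kidney_density g/L
#' @slot renal_scale kidney-mass inter-individual scalar (mean about 1)
#'   applied to active renal secretion
#' @slot gi named numeric vector of GI residence times (h); the colon drug
#'   mean residence time is the sex-appropriate one
#' @slot phenotypes named character vector, target -> phenotype
#' @slot oat3_fraction fraction (0-1) of healthy OAT-mediated secretion
#' @export
setClass("VirtualIndividual", representation(
  sex = "character", age = "numeric", bh = "numeric", bw = "numeric",
  scr = "numeric", egfr = "numeric", hematocrit = "numeric",
  hsa = "numeric", agp = "numeric", hsa_ref = "numeric", agp_ref = "numeric",
  kidney_volume = "numeric", kidney_density = "numeric",
  renal_scale = "numeric", gi = "numeric", phenotypes = "character",
  oat3_fraction = "numeric"))

setValidity("VirtualIndividual", function(object) {
  msg <- character()
  if (!object@sex %in% c("M", "F")) msg <- c(msg, "sex must be M or F")
  if (object@age < 18 || object@age > 100) msg <- c(msg, "age must lie in [18, 100]")
  if (object@oat3_fraction < 0 || object@oat3_fraction > 1)
    msg <- c(msg, "oat3_fraction must lie in [0, 1]")
  if (object@scr <= 0) msg <- c(msg, "scr must be positive")
  if (object@hematocrit <= 0 || object@hematocrit >= 1)
    msg <- c(msg, "hematocrit must be a fraction in (0, 1)")
  if (abs(object@egfr - computeEGFR(object@scr, object@age, object@sex)) > 1e-6)
    msg <- c(msg, "egfr inconsistent with scr/age/sex under CKD-EPI")
  if (length(msg)) msg else TRUE
})

#' Enzyme/transporter abundance profile
#'
#' One row per (target, tissue): abundance (absolute, or relative for ileum
#' BCRP) and the phenotype activity scores. The ESRD profile is derived from
#' the healthy-volunteer profile by target-specific multipliers only.
#'
#' @slot entries data.frame with columns target, tissue, abundance,
#'   `EM/T`, `PM/T`, `IM/T`, `UM/T`
#' @slot label "HV" or "ESRD"
#' @export
setClass("DMETProfile", representation(entries = "data.frame", label = "character"))

setValidity("DMETProfile", function(object) {
  e <- object@entries
  msg <- character()
  need <- c("target", "tissue", "abundance", "EM/T", "PM/T", "IM/T", "UM/T")
  if (!all(need %in% names(e))) return(paste("entries must have columns", paste(need, collapse = ", ")))
  if (anyDuplicated(paste(e$target, e$tissue))) msg <- c(msg, "each (target, tissue) must appear once")
  if (any(e$abundance < 0)) msg <- c(msg, "abundances must be non-negative")
  if (any(as.matrix(e[, c("EM/T", "PM/T", "IM/T", "UM/T")]) < 0))
    msg <- c(msg, "activity scores must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Drug disposition model
#'
#' Per-drug parameters of the reduced PBPK model. Intrinsic clearances are
#' held in a named list keyed `"TARGET.tissue"` (e.g. `"OATP1B1.liver"`),
#' in uL/min/pmol for enzymes and uL/min/10^6 cells for transporters; they
#' are scaled to whole-organ clearances through the profile abundances and
#' the tissue scaling constants in [pbpkScales()].
#'
#' @slot name drug label
#' @slot mw molecular weight, g/mol
#' @slot fu_hv unbound plasma fraction in healthy volunteers
#' @slot fu_esrd_ratio ESRD/HV ratio of fu (1 = unchanged)
#' @slot binding_protein "HSA", "AGP" or "none": protein whose level drives
#'   inter-individual fu scaling
#' @slot blood_plasma_ratio blood:plasma concentration ratio (metadata in the
#'   reduced plasma-based model)
#' @slot ka first-order absorption rate from lumen into enterocyte, 1/h
#' @slot colon_ka_factor multiplier on ka in the colon segment
#' @slot vss central distribution volume coefficient, L/kg
#' @slot kp_muscle muscle:plasma partition coefficient (0 = no muscle
#'   compartment)
#' @slot ps_liver passive sinusoidal permeability-surface product, L/h
#' @slot clint named list "TARGET.tissue" -> intrinsic clearance
#' @slot cl_met_other additional hepatic intracellular clearance (L/h, acts
#'   on intracellular concentration) for metabolism not mapped to a profiled
#'   enzyme (e.g. glucuronidation)
#' @slot cl_extra additional linear systemic plasma clearance, L/h
#' @slot renal_filtration logical; include fu x GFR filtration
#' @slot prodrug_conversion_k first-order prodrug-to-active conversion rate
#'   (1/h); 0 for non-prodrugs. For prodrugs the gut/efflux parameters act on
#'   the prodrug and the systemic disposition on the active moiety.
#' @export
setClass("DrugModel", representation(
  name = "character", mw = "numeric", fu_hv = "numeric",
  fu_esrd_ratio = "numeric", binding_protein = "character",
  blood_plasma_ratio = "numeric", ka = "numeric", colon_ka_factor = "numeric",
  vss = "numeric", kp_muscle = "numeric", ps_liver = "numeric",
  clint = "list", cl_met_other = "numeric", cl_extra = "numeric",
  renal_filtration = "logical", prodrug_conversion_k = "numeric"))

setValidity("DrugModel", function(object) {
  msg <- character()
  if (object@fu_hv <= 0 || object@fu_hv > 1) msg <- c(msg, "fu_hv must lie in (0, 1]")
  if (object@fu_hv * object@fu_esrd_ratio > 1 + 1e-9)
    msg <- c(msg, "fu_hv * fu_esrd_ratio must not exceed 1")
  if (!object@binding_protein %in% c("HSA", "AGP", "none"))
    msg <- c(msg, "binding_protein must be HSA, AGP or none")
  if (length(object@clint) && any(unlist(object@clint) < 0))
    msg <- c(msg, "intrinsic clearances must be non-negative")
  if (any(c(object@ka, object@vss, object@kp_muscle, object@ps_liver,
            object@cl_met_other, object@cl_extra, object@prodrug_conversion_k) < 0))
    msg <- c(msg, "rates, volumes and clearances must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Perpetrator (inhibitor) exposure
#'
#' Static unbound perpetrator exposure with competitive inhibition constants
#' per target and optional mechanism-based inactivation (MBI) handled as a
#' steady-state enzyme-amount attenuation.
#'
#' @slot name perpetrator label
#' @slot iu static unbound concentration, uM
#' @slot ki named numeric, target -> competitive Ki (uM, unbound)
#' @slot mbi named list, target -> list(KI = uM, kinact = 1/h), or empty
#' @slot kdeg enzyme turnover rate for MBI attenuation, 1/h
#' @export
setClass("InhibitorExposure", representation(
  name = "character", iu = "numeric", ki = "numeric", mbi = "list",
  kdeg = "numeric"))

setValidity("InhibitorExposure", function(object) {
  msg <- character()
  if (object@iu < 0) msg <- c(msg, "iu must be non-negative")
  if (length(object@ki) && any(object@ki <= 0)) msg <- c(msg, "ki values must be positive")
  for (m in object@mbi)
    if (m$KI <= 0 || m$kinact < 0) msg <- c(msg, "MBI needs KI > 0 and kinact >= 0")
  if (object@kdeg <= 0) msg <- c(msg, "kdeg must be positive")
  if (length(msg)) msg else TRUE
})

#' Dose regimen
#'
#' @slot route "oral" or "iv"
#' @slot amount dose per administration, mg
#' @slot times administration times, h (sorted)
#' @export
setClass("DoseRegimen", representation(
  route = "character", amount = "numeric", times = "numeric"))

setValidity("DoseRegimen", function(object) {
  msg <- character()
  if (!object@route %in% c("oral", "iv")) msg <- c(msg, "route must be oral or iv")
  if (object@amount <= 0) msg <- c(msg, "amount must be positive")
  if (is.unsorted(object@times)) msg <- c(msg, "times must be sorted")
  if (length(msg)) msg else TRUE
})

#' Simulation result
#'
#' Concentration-time series per compartment plus cumulative amount
#' eliminated per pathway, on a fixed output grid.
#'
#' @slot t time grid, h
#' @slot conc named list of concentration series (mg/L): `plasma`, `muscle`
#' @slot eliminated matrix (time x pathway) of cumulative eliminated
#'   amounts, mg
#' @slot residual matrix (time x compartment) of amounts still in the
#'   system, mg (for mass-balance auditing)
#' @slot dose_total administered dose, mg
#' @export
setClass("SimulationResult", representation(
  t = "numeric", conc = "list", eliminated = "matrix",
  residual = "matrix", dose_total = "numeric"))

setValidity("SimulationResult", function(object) {
  msg <- character()
  if (any(vapply(object@conc, function(x) any(x < -1e-9), logical(1))))
    msg <- c(msg, "concentrations must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Individual clearance correction equation
#'
#' Linear model for the CL/F ratio (PBPK-predicted over reference): ratio =
#' intercept + sum(coefficient x covariate), in the covariates' raw units.
#' The corrected clearance divides the PBPK clearance by the predicted
#' ratio.
#'
#' @slot drug drug label
#' @slot intercept dimensionless
#' @slot coefficients named numeric, covariate -> slope
#' @export
setClass("CorrectionEquation", representation(
  drug = "character", intercept = "numeric", coefficients = "numeric"))

setValidity("CorrectionEquation", function(object) {
  if (!all(is.finite(c(object@intercept, object@coefficients))))
    "intercept and coefficients must be finite" else TRUE
})
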