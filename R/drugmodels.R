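#' Construct a drug disposition model
#'
#' @param name drug label
#' @param mw molecular weight, g/mol
#' @param fu_hv unbound plasma fraction in healthy volunteers
#' @param fu_esrd_ratio ESRD/HV fu ratio
#' @param binding_protein "HSA", "AGP" or "none"
#' @param blood_plasma_ratio blood:plasma ratio
#' @param ka absorption rate constant, 1/h
#' @param colon_ka_factor colon absorption multiplier on ka
#' @param vss central volume coefficient, L/kg
#' @param kp_muscle muscle:plasma partition coefficient
#' @param ps_liver passive sinusoidal permeability, L/h
#' @param clint named list "TARGET.tissue" -> intrinsic clearance
#' @param cl_met_other unprofiled hepatic intracellular clearance, L/h
#' @param cl_extra additional systemic plasma clearance, L/h
#' @param renal_filtration include fu x GFR filtration
#' @param prodrug_conversion_k prodrug-to-active conversion rate, 1/h
#' @return a [DrugModel-class]
#' @export
drugModel <- function(name, mw, fu_hv, fu_esrd_ratio = 1,
                      binding_protein = "HSA", blood_plasma_ratio = 1,
                      ka = 1, colon_ka_factor = 0.1, vss = 1, kp_muscle = 0,
                      ps_liver = 0, clint = list(), cl_met_other = 0,
                      cl_extra = 0, renal_filtration = TRUE,
                      prodrug_conversion_k = 0) {
  new("DrugModel", name = name, mw = mw, fu_hv = fu_hv,
      fu_esrd_ratio = fu_esrd_ratio, binding_protein = binding_protein,
      blood_plasma_ratio = blood_plasma_ratio, ka = ka,
      colon_ka_factor = colon_ka_factor, vss = vss, kp_muscle = kp_muscle,
      ps_liver = ps_liver, clint = clint, cl_met_other = cl_met_other,
      cl_extra = cl_extra, renal_filtration = renal_filtration,
      prodrug_conversion_k = prodrug_conversion_k)
}

#' Probe-substrate drug fixtures
#'
#' Five archetype drug models matching the microdose-cocktail probes:
#' \describe{
#'   \item{midazolam}{CYP3A4-only elimination (liver + gut wall).}
#'   \item{dabigatran}{prodrug (etexilate) with jejunal P-gp efflux and
#'     lumped first-order conversion to the renally cleared active moiety;
#'     plasma protein binding unchanged in ESRD.}
#'   \item{pitavastatin}{hepatic OATP1B1/3 uptake-limited clearance with
#'     unprofiled (glucuronidation) intracellular loss.}
#'   \item{rosuvastatin}{OATP1B uptake, biliary BCRP efflux, ileal BCRP
#'     absorption-limiting efflux, and renal OAT3-mediated secretion
#'     (CLint,T 150 uL/min/10^6 cells) tuned so the renal route carries
#'     about 28\% of total clearance in healthy volunteers.}
#'   \item{atorvastatin}{multi-pathway: CYP3A4 (liver + gut), OATP1B
#'     uptake, ileal BCRP efflux (CLint,T 6 uL/min) and jejunal P-gp.}
#' }
#' Printed literature anchors are used where available; remaining values
#' are documented plausible placeholders — pathway-ratio behaviour, not
#' absolute clinical exposure, is the modelled quantity.
#'
#' @param name one of "midazolam", "dabigatran", "pitavastatin",
#'   "rosuvastatin", "atorvastatin"
#' @return a [DrugModel-class]
#' @export
drugFixture <- function(name = c("midazolam", "dabigatran", "pitavastatin",
                                 "rosuvastatin", "atorvastatin")) {
  name <- match.arg(name)
  switch(name,
    midazolam = drugModel("midazolam", mw = 325.8, fu_hv = 0.03,
      fu_esrd_ratio = 1.2, binding_protein = "HSA", blood_plasma_ratio = 0.66,
      ka = 2, vss = 1.0, ps_liver = 3000,
      clint = list("CYP3A4.liver" = 5.6, "CYP3A4.intestine" = 2.0,
                   "CYP3A4.colon" = 2.0),
      renal_filtration = FALSE),
    dabigatran = drugModel("dabigatran", mw = 627.7, fu_hv = 0.65,
      fu_esrd_ratio = 1.0, binding_protein = "none", blood_plasma_ratio = 0.71,
      ka = 0.4, vss = 0.9,
      clint = list("P-gp.jejunum" = 22.5),
      cl_extra = 1.5, renal_filtration = TRUE, prodrug_conversion_k = 10),
    pitavastatin = drugModel("pitavastatin", mw = 421.5, fu_hv = 0.01,
      fu_esrd_ratio = 1.25, binding_protein = "HSA", blood_plasma_ratio = 0.6,
      ka = 1.2, vss = 0.6, kp_muscle = 0.25, ps_liver = 30,
      clint = list("OATP1B1.liver" = 6.1, "OATP1B3.liver" = 6.1),
      cl_met_other = 40, renal_filtration = FALSE),
    rosuvastatin = drugModel("rosuvastatin", mw = 481.5, fu_hv = 0.12,
      fu_esrd_ratio = 1.15, binding_protein = "HSA", blood_plasma_ratio = 0.69,
      ka = 0.3, vss = 0.5, kp_muscle = 0.25, ps_liver = 5,
      clint = list("OATP1B1.liver" = 0.35, "OATP1B3.liver" = 0.35,
                   "BCRP.liver" = 3, "BCRP.ileum" = 3,
                   "OAT3.renal" = 150, "BCRP.renal" = 10),
      cl_met_other = 2, renal_filtration = TRUE),
    atorvastatin = drugModel("atorvastatin", mw = 558.6, fu_hv = 0.05,
      fu_esrd_ratio = 1.2, binding_protein = "HSA", blood_plasma_ratio = 0.61,
      ka = 1.5, vss = 0.8, kp_muscle = 0.25, ps_liver = 40,
      clint = list("CYP3A4.liver" = 2, "CYP3A4.intestine" = 1.0,
                   "CYP3A4.colon" = 1.0, "OATP1B1.liver" = 8,
                   "OATP1B3.liver" = 8, "P-gp.liver" = 2, "BCRP.liver" = 3,
                   "BCRP.ileum" = 6, "P-gp.jejunum" = 10),
      renal_filtration = FALSE))
}

#' Perpetrator (inhibitor) fixtures
#'
#' Static-exposure perpetrator models with competitive inhibition constants
#' and, for clarithromycin, mechanism-based CYP3A4 inactivation handled as
#' a steady-state enzyme-amount attenuation (default enzyme turnover
#' 0.03 1/h). Unbound exposures and interaction constants are documented
#' placeholders of the right order; scenario conclusions are directional.
#'
#' @param name one of "rifampin", "itraconazole", "clarithromycin",
#'   "ritonavir", "verapamil"
#' @param iu optional static unbound concentration override, uM
#' @return an [InhibitorExposure-class]
#' @export
inhibitorFixture <- function(name = c("rifampin", "itraconazole",
                                      "clarithromycin", "ritonavir",
                                      "verapamil"), iu = NULL) {
  name <- match.arg(name)
  x <- switch(name,
    rifampin = list(iu = 2.0,
      ki = c("OATP1B1" = 0.5, "OATP1B3" = 0.5), mbi = list()),
    itraconazole = list(iu = 0.02,
      ki = c("CYP3A4" = 0.0013, "P-gp" = 0.008), mbi = list()),
    clarithromycin = list(iu = 1.0,
      ki = c("P-gp" = 4.1, "OATP1B1" = 8.0, "OATP1B3" = 8.0),
      mbi = list("CYP3A4" = list(KI = 5.5, kinact = 3.24))),
    ritonavir = list(iu = 0.1,
      ki = c("CYP3A4" = 0.019), mbi = list()),
    verapamil = list(iu = 0.1,
      ki = c("CYP3A4" = 2.0, "P-gp" = 1.0), mbi = list()))
  new("InhibitorExposure", name = name, iu = if (is.null(iu)) x$iu else iu,
      ki = x$ki, mbi = x$mbi, kdeg = 0.03)
}

#' Construct a dose regimen
#'
#' @param route "oral" or "iv"
#' @param amount dose per administration, mg
#' @param n_doses number of doses
#' @param interval dosing interval, h (ignored for single dose)
#' @param start first dose time, h
#' @return a [DoseRegimen-class]
#' @export
doseRegimen <- function(route = "oral", amount, n_doses = 1, interval = 24,
                        start = 0) {
  new("DoseRegimen", route = route, amount = amount,
      times = start + interval * (seq_len(n_doses) - 1))
}

#' Microdose-cocktail regimens
#'
#' Single oral microdoses of the five probes: 10 ug midazolam, 375 ug
#' dabigatran etexilate, 10 ug pitavastatin, 50 ug rosuvastatin and 100 ug
#' atorvastatin (amounts in mg).
#'
#' @param name drug fixture name
#' @return a [DoseRegimen-class]
#' @export
microdoseRegimen <- function(name = c("midazolam", "dabigatran",
                                      "pitavastatin", "rosuvastatin",
                                      "atorvastatin")) {
  name <- match.arg(name)
  amount <- c(midazolam = 0.010, dabigatran = 0.375, pitavastatin = 0.010,
              rosuvastatin = 0.050, atorvastatin = 0.100)[[name]]
  doseRegimen("oral", amount)
}
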