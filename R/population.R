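#' Lognormal sample matching a mean and CV
#'
#' Draws from a lognormal distribution parameterised so that its arithmetic
#' mean and coefficient of variation equal the supplied values. This is the
#' convention used throughout the population sampler for any "(mean, CV\%)"
#' physiological parameter: it guarantees positivity.
#'
#' @param n number of draws
#' @param mean arithmetic mean
#' @param cv coefficient of variation, percent
#' @return numeric vector of length `n`
#' @export
rlnormMeanCV <- function(n, mean, cv) {
  if (mean <= 0) stop("mean must be positive")
  if (cv <= 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + (cv / 100)^2))
  rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Deterministic body size from the demographic polynomials
#'
#' Evaluates the sex-specific height polynomial (cm vs years) and then the
#' weight log-linear model (kg vs cm). Population sampling adds lognormal
#' inter-individual variability separately; this function is the
#' deterministic typical value.
#'
#' @param sex "M" or "F"
#' @param age years, in [18, 100]
#' @param demographics a [DemographicModel-class]; defaults to the CK-NET
#'   ESRD demographic equations
#' @return named numeric `c(bh = , bw = )` (cm, kg)
#' @examples
#' predictBodySize("M", 40)
#' @export
predictBodySize <- function(sex, age, demographics = esrdDemographics()) {
  if (!sex %in% c("M", "F")) stop("sex must be 'M' or 'F'")
  if (!is.finite(age) || age < 18 || age > 100) stop("age must lie in [18, 100]")
  h <- demographics@height[[sex]]
  w <- demographics@weight[[sex]]
  bh <- h[1] + h[2] * age + h[3] * age^2
  bw <- exp(w[1] + w[2] * bh)
  c(bh = unname(bh), bw = unname(bw))
}

#' CKD-EPI 2009 estimated glomerular filtration rate
#'
#' Creatinine-based CKD-EPI 2009 equation without the race coefficient
#' (Chinese population). Serum creatinine in umol/L is converted to mg/dL by
#' dividing by 88.4.
#'
#' @param scr serum creatinine, umol/L (> 0)
#' @param age years
#' @param sex "M" or "F"
#' @return eGFR, mL/min/1.73 m^2
#' @examples
#' computeEGFR(88.4, 40, "M")   # about 93.7
#' computeEGFR(721.69, 50, "F") # about 5.2
#' @export
computeEGFR <- function(scr, age, sex) {
  if (any(scr <= 0)) stop("scr must be positive")
  if (!sex %in% c("M", "F")) stop("sex must be 'M' or 'F'")
  scr_mgdl <- scr / 88.4
  kappa <- if (sex == "F") 0.7 else 0.9
  alpha <- if (sex == "F") -0.329 else -0.411
  sk <- scr_mgdl / kappa
  egfr <- 141 * pmin(sk, 1)^alpha * pmax(sk, 1)^(-1.209) * 0.993^age
  if (sex == "F") egfr <- egfr * 1.018
  egfr
}

#' Fractional renal OAT-mediated secretory function from eGFR
#'
#' The eGFR-based scaling of active renal (OAT3) secretion:
#' `1 - exp(-(egfr / 43.9)^0.9)`, returned on the 0-1 scale. It is strictly
#' increasing in eGFR and asymptotes to 1 at preserved kidney function; at
#' the Chinese ESRD mean eGFR of 10.81 mL/min/1.73 m^2 it evaluates to
#' about 0.247 of healthy function.
#'
#' @param egfr mL/min/1.73 m^2, non-negative
#' @return fraction in [0, 1)
#' @examples
#' oat3Fraction(10.81)
#' oat3Fraction(43.9) # 1 - exp(-1)
#' @export
oat3Fraction <- function(egfr) {
  if (any(egfr < 0)) stop("egfr must be non-negative")
  1 - exp(-(egfr / 43.9)^0.9)
}

#' CK-NET ESRD demographic equations
#' @return a [DemographicModel-class]
#' @export
esrdDemographics <- function() {
  new("DemographicModel",
      height = list(M = c(176.18, -0.2623, 0.0016),
                    F = c(161.15, -0.1405, 0.0005)),
      weight = list(M = c(1.9619, 0.01314),
                    F = c(2.442, 0.01000)))
}

#' Chinese ESRD population specification
#'
#' Demographics and creatinine strata from the CK-NET 2016 report; blood
#' chemistry from Chinese outpatient ESRD data; kidney-size parameters from
#' the severe-renal-impairment stage; GI residence times prolonged relative
#' to healthy volunteers. The overlapping printed female creatinine age
#' bands are normalised to disjoint bands [18,30), [30,60), [60,Inf)
#' (most-specific-band-wins); male bands are [18,50), [50,Inf).
#'
#' @return a [PopulationSpec-class]
#' @export
esrdPopulationSpec <- function() {
  new("PopulationSpec",
      label = "ESRD",
      demographics = esrdDemographics(),
      creatinine = data.frame(
        sex  = c("M", "M", "F", "F", "F"),
        lo   = c(18, 50, 18, 30, 60),
        hi   = c(50, Inf, 30, 60, Inf),
        mean = c(800, 674.74, 800, 666.80, 533.32),
        cv   = c(38.4, 42.45, 27.85, 33.44, 34.01)),
      blood = data.frame(
        sex = c("M", "F"),
        hct_mean = c(33.1, 32.7), hct_cv = c(17.18, 16.49),
        agp_mean = c(1.0388, 1.0948), agp_cv = c(39.00, 34.08),
        hsa_mean = c(35.12, 34.43), hsa_cv = c(27.38, 26.75)),
      kidney = c(baseline = 5.7, bw_coeff = 1.04, bh_coeff = 29.8,
                 cv = 23.4, density = 1050),
      gi = c(gastric_fasted = 0.80, gastric_fed = 3.35, colon_residence = 30,
             colon_mrt_male = 36.72, colon_mrt_female = 50.14),
      phenotype_freq = defaultPhenotypeFreq(),
      age_range = c(20, 70), female_fraction = 0.5,
      height_cv = 3, weight_cv = 15)
}

#' Chinese healthy-volunteer population specification
#'
#' Comparator population. Values not specific to ESRD (creatinine, blood
#' chemistry, kidney-size coefficients, GI residence) are representative
#' healthy Chinese adult values; the ESRD GI residence times are
#' prolongations of these (gastric x2, colon drug mean residence x1.5).
#'
#' @return a [PopulationSpec-class]
#' @export
hvPopulationSpec <- function() {
  new("PopulationSpec",
      label = "HV",
      demographics = new("DemographicModel",
        height = list(M = c(178.1, -0.26, 0.0015), F = c(163.5, -0.14, 0.0005)),
        weight = list(M = c(1.9619, 0.01314), F = c(2.442, 0.01000))),
      creatinine = data.frame(
        sex  = c("M", "F"),
        lo   = c(18, 18), hi = c(Inf, Inf),
        mean = c(75, 60), cv = c(12, 12)),
      blood = data.frame(
        sex = c("M", "F"),
        hct_mean = c(45.0, 40.0), hct_cv = c(6, 6),
        agp_mean = c(0.65, 0.65), agp_cv = c(25, 25),
        hsa_mean = c(48.5, 47.5), hsa_cv = c(7, 7)),
      kidney = c(baseline = 5.7, bw_coeff = 2.9, bh_coeff = 65,
                 cv = 18, density = 1050),
      gi = c(gastric_fasted = 0.40, gastric_fed = 1.675, colon_residence = 20,
             colon_mrt_male = 24.48, colon_mrt_female = 33.43),
      phenotype_freq = defaultPhenotypeFreq(),
      age_range = c(20, 70), female_fraction = 0.5,
      height_cv = 3, weight_cv = 15)
}

#' Default phenotype frequencies (all extensive metabolisers/transporters)
#' @return named list target -> probability vector
#' @export
defaultPhenotypeFreq <- function() {
  p <- c("EM/T" = 1, "PM/T" = 0, "IM/T" = 0, "UM/T" = 0)
  list(CYP3A4 = p, OATP1B1 = p, OATP1B3 = p, `P-gp` = p, BCRP = p, OAT3 = p)
}

.sampleIndividualDraws <- function(spec) {
  # Fixed draw layout so that two specs consume identical random-number
  # streams (common random numbers for matched HV/ESRD cohorts).
  age <- runif(1, spec@age_range[1], spec@age_range[2])
  sex <- if (runif(1) < spec@female_fraction) "F" else "M"
  base <- predictBodySize(sex, age, spec@demographics)
  bh <- base[["bh"]] * rlnormMeanCV(1, 1, spec@height_cv)
  bw <- exp(spec@demographics@weight[[sex]][1] +
              spec@demographics@weight[[sex]][2] * bh) *
    rlnormMeanCV(1, 1, spec@weight_cv)
  cs <- spec@creatinine[spec@creatinine$sex == sex, , drop = FALSE]
  row <- cs[cs$lo <= age & age < cs$hi, , drop = FALSE]
  if (nrow(row) != 1) stop(sprintf("no creatinine stratum covering (%s, %.1f)", sex, age))
  scr <- rlnormMeanCV(1, row$mean, row$cv)
  bl <- spec@blood[spec@blood$sex == sex, , drop = FALSE]
  hct <- rlnormMeanCV(1, bl$hct_mean, bl$hct_cv) / 100
  hct <- min(hct, 0.65)
  hsa <- rlnormMeanCV(1, bl$hsa_mean, bl$hsa_cv)
  agp <- rlnormMeanCV(1, bl$agp_mean, bl$agp_cv)
  k <- spec@kidney
  kv_det <- k[["baseline"]] + k[["bw_coeff"]] * bw + k[["bh_coeff"]] * (bh / 100)
  kv <- kv_det * rlnormMeanCV(1, 1, k[["cv"]])
  phen <- vapply(names(spec@phenotype_freq), function(tg) {
    p <- spec@phenotype_freq[[tg]]
    sample(names(p), 1, prob = p)
  }, character(1))
  egfr <- computeEGFR(scr, age, sex)
  gi <- c(gastric = spec@gi[["gastric_fasted"]],
          colon_residence = spec@gi[["colon_residence"]],
          colon_mrt = if (sex == "M") spec@gi[["colon_mrt_male"]] else spec@gi[["colon_mrt_female"]])
  new("VirtualIndividual",
      sex = sex, age = age, bh = bh, bw = bw, scr = scr, egfr = egfr,
      hematocrit = hct, hsa = hsa, agp = agp,
      hsa_ref = bl$hsa_mean, agp_ref = bl$agp_mean,
      kidney_volume = kv, kidney_density = k[["density"]],
      renal_scale = kv / kv_det, gi = gi, phenotypes = phen,
      oat3_fraction = if (spec@label == "ESRD") oat3Fraction(egfr) else 1.0)
}

#' Sample one virtual individual
#'
#' @param spec a [PopulationSpec-class]
#' @param seed optional integer; when given, sampling is seeded locally and
#'   bit-reproducible
#' @return a [VirtualIndividual-class]
#' @export
sampleIndividual <- function(spec, seed = NULL) {
  validObject(spec)
  if (!is.null(seed)) return(withSeed(seed, .sampleIndividualDraws(spec)))
  .sampleIndividualDraws(spec)
}

#' Sample a virtual cohort
#'
#' Individuals are drawn with a fixed per-individual random-number layout,
#' so two cohorts sampled from different specs under the same seed are
#' matched subject-by-subject (common random numbers): the same underlying
#' deviates drive age, sex, body size, creatinine, blood chemistry and
#' kidney volume in both populations.
#'
#' @param spec a [PopulationSpec-class]
#' @param n number of subjects
#' @param seed optional integer seed
#' @return list of [VirtualIndividual-class]
#' @export
sampleCohort <- function(spec, n, seed = NULL) {
  validObject(spec)
  run <- function() lapply(seq_len(n), function(i) .sampleIndividualDraws(spec))
  if (!is.null(seed)) withSeed(seed, run()) else run()
}

#' A deterministic reference healthy individual
#'
#' Typical-value 40-year-old subject of the requested sex with population
#' mean blood chemistry and eGFR; useful for degenerate-configuration tests
#' and sensitivity analysis baselines.
#'
#' @param sex "M" or "F"
#' @param spec population spec supplying the typical values
#' @return a [VirtualIndividual-class]
#' @export
referenceIndividual <- function(sex = "M", spec = hvPopulationSpec()) {
  age <- 40
  base <- predictBodySize(sex, age, spec@demographics)
  cs <- spec@creatinine[spec@creatinine$sex == sex, , drop = FALSE]
  row <- cs[cs$lo <= age & age < cs$hi, , drop = FALSE]
  bl <- spec@blood[spec@blood$sex == sex, , drop = FALSE]
  k <- spec@kidney
  kv <- k[["baseline"]] + k[["bw_coeff"]] * base[["bw"]] + k[["bh_coeff"]] * (base[["bh"]] / 100)
  egfr <- computeEGFR(row$mean, age, sex)
  new("VirtualIndividual",
      sex = sex, age = age, bh = base[["bh"]], bw = base[["bw"]],
      scr = row$mean, egfr = egfr,
      hematocrit = bl$hct_mean / 100, hsa = bl$hsa_mean, agp = bl$agp_mean,
      hsa_ref = bl$hsa_mean, agp_ref = bl$agp_mean,
      kidney_volume = kv, kidney_density = k[["density"]], renal_scale = 1,
      gi = c(gastric = spec@gi[["gastric_fasted"]],
             colon_residence = spec@gi[["colon_residence"]],
             colon_mrt = if (sex == "M") spec@gi[["colon_mrt_male"]] else spec@gi[["colon_mrt_female"]]),
      phenotypes = vapply(names(spec@phenotype_freq), function(tg) "EM/T", character(1)),
      oat3_fraction = if (spec@label == "ESRD") oat3Fraction(egfr) else 1.0)
}

#' Export a cohort as a data frame
#'
#' One row per subject with columns named after the individual fields;
#' suitable for CSV export.
#'
#' @param cohort list of [VirtualIndividual-class]
#' @return data.frame
#' @export
cohortTable <- function(cohort) {
  do.call(rbind, lapply(seq_along(cohort), function(i) {
    x <- cohort[[i]]
    data.frame(subject = i, sex = x@sex, age = x@age, bh = x@bh, bw = x@bw,
               scr = x@scr, egfr = x@egfr, hematocrit = x@hematocrit,
               hsa = x@hsa, agp = x@agp, kidney_volume = x@kidney_volume,
               oat3_fraction = x@oat3_fraction,
               gastric_rt = x@gi[["gastric"]], colon_mrt = x@gi[["colon_mrt"]])
  }))
}

# Evaluate an expression under a local, restored RNG state.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
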