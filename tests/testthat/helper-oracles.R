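# Shared fixtures and independent oracles used across the suite.

refInd <- function(sex = "M") referenceIndividual(sex)
hvProf <- hvDmetProfile()
esrdProf <- esrdDmetProfile()

# Independent per-interval AUC oracle: literal rule application, written
# separately from the vectorised implementation.
bruteForceAUC <- function(t, c) {
  total <- 0
  for (i in seq_len(length(t) - 1)) {
    c1 <- c[i]; c2 <- c[i + 1]; dt <- t[i + 1] - t[i]
    a <- if (c2 < c1 && c1 > 0 && c2 > 0) (c1 - c2) / log(c1 / c2) * dt
         else (c1 + c2) / 2 * dt
    total <- total + a
  }
  total
}

# Closed-form one-compartment oral model (absorption ka, elimination k).
oneCptOral <- function(t, dose, ka, cl_f, v_f) {
  k <- cl_f / v_f
  dose * ka / (v_f * (ka - k)) * (exp(-k * t) - exp(-ka * t))
}

# Closed-form two-compartment iv bolus: central V1 with clearance CL,
# peripheral V2 linked by inter-compartmental clearance Q.
twoCptIvBolus <- function(t, dose, cl, v1, v2, q) {
  k10 <- cl / v1; k12 <- q / v1; k21 <- q / v2
  s <- k10 + k12 + k21
  alpha <- (s + sqrt(s^2 - 4 * k10 * k21)) / 2
  beta <- (s - sqrt(s^2 - 4 * k10 * k21)) / 2
  A <- dose / v1 * (alpha - k21) / (alpha - beta)
  B <- dose / v1 * (k21 - beta) / (alpha - beta)
  A * exp(-alpha * t) + B * exp(-beta * t)
}

# Minimal iv test drug: single systemic clearance CL (L/h) and central
# volume V (L) for the supplied individual; everything else off.
degenerateIvDrug <- function(cl, v, individual = refInd(), kp_muscle = 0) {
  drugModel("degenerate", mw = 300, fu_hv = 0.5, binding_protein = "none",
            vss = v / individual@bw, kp_muscle = kp_muscle, cl_extra = cl,
            renal_filtration = FALSE)
}

ivBolus <- function(amount = 10) new("DoseRegimen", route = "iv",
                                     amount = amount, times = 0)

# Toy single-entry profile/drug pair for effectiveClint unit checks.
toyProfile <- function(abundance = 1, em = 1) {
  e <- data.frame(target = "CYP3A4", tissue = "liver", abundance = abundance,
                  `EM/T` = em, `PM/T` = 0, `IM/T` = 0, `UM/T` = 0,
                  check.names = FALSE)
  new("DMETProfile", entries = e, label = "HV")
}

# Four-candidate recovery study: two planted genera (sharing a community
# factor) plus one nuisance genus and one nuisance lab.
recoveryStudySpec <- function(noise_cv = 2) {
  syntheticStudySpec(
    noise_cv = noise_cv,
    microbiome = data.frame(
      genus = c("Clostridium_XVIII", "Escherichia", "Bacteroides"),
      meanlog = log(c(2, 5.7, 20)), sdlog = c(0.4, 0.4, 0.5),
      w = c(0.8, 0.8, 0)),
    labs = data.frame(lab = "AST", mean = 22, cv = 30))
}
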