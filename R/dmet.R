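#' Healthy-volunteer enzyme/transporter abundance profile
#'
#' Baseline Chinese healthy-volunteer abundances and phenotype activity
#' scores for CYP3A4 (liver/intestine/colon), OATP1B1/3 (liver), P-gp
#' (liver/jejunum), BCRP (ileum/liver/renal) and OAT3 (renal). Abundances
#' are absolute (pmol/mg microsomal protein for enzymes, pmol/10^6 cells
#' for transporters) except ileum BCRP, which is a relative abundance
#' versus jejunum.
#'
#' @return a [DMETProfile-class] labelled "HV"
#' @export
hvDmetProfile <- function() {
  e <- data.frame(
    target = c("CYP3A4", "CYP3A4", "CYP3A4", "OATP1B1", "OATP1B3",
               "P-gp", "P-gp", "BCRP", "BCRP", "BCRP", "OAT3"),
    tissue = c("liver", "intestine", "colon", "liver", "liver",
               "liver", "jejunum", "ileum", "liver", "renal", "renal"),
    abundance = c(120, 57.3, 2.58, 3.1, 3.08, 0.246, 0.4, 0.78, 0.103, 0.120, 1.320),
    `EM/T` = c(1, 1, 1, 0.584, 1, 1, 1, 1, 1, 1, 1),
    `PM/T` = c(0, 0, 0, 0.21, 0, 0, 0, 0.37, 0.37, 0.37, 0),
    `IM/T` = c(0, 0, 0, 0.4, 0, 0, 0, 0.67, 0.67, 0.67, 0),
    `UM/T` = c(0, 0, 0, 0.81, 0, 0, 0, 0, 0, 0, 0),
    check.names = FALSE)
  new("DMETProfile", entries = e, label = "HV")
}

#' Apply an abundance or activity multiplier to a profile
#'
#' Scales one (target, tissue) entry of a profile. `mode = "activity"`
#' multiplies every phenotype activity score (the convention for functional
#' changes of enzymes and uptake/efflux transporters); `mode = "abundance"`
#' multiplies the abundance itself (the convention for the ileum BCRP
#' relative abundance). Simulated exposure depends only on the product, so
#' the two modes are exposure-equivalent; the mode fixes which printed cell
#' of the profile changes.
#'
#' OATP1B1 and OATP1B3 are locked together: a multiplier addressed to
#' either (or to the pseudo-target "OATP1B") is applied to both, reflecting
#' the assumption that their functions change synchronously with identical
#' folds.
#'
#' @param profile a [DMETProfile-class]
#' @param target target name; "OATP1B" addresses the locked OATP1B1/3 pair
#' @param tissue tissue name (ignored for the OATP1B pair, which is hepatic)
#' @param multiplier non-negative scalar
#' @param mode "activity" or "abundance"
#' @param label optional new profile label
#' @return modified [DMETProfile-class]
#' @export
applyAbundanceMultiplier <- function(profile, target, tissue, multiplier,
                                     mode = c("activity", "abundance"),
                                     label = profile@label) {
  mode <- match.arg(mode)
  if (multiplier < 0) stop("multiplier must be non-negative")
  e <- profile@entries
  if (target %in% c("OATP1B", "OATP1B1", "OATP1B3")) {
    idx <- which(e$target %in% c("OATP1B1", "OATP1B3"))
  } else {
    idx <- which(e$target == target & e$tissue == tissue)
  }
  if (!length(idx)) stop(sprintf("no profile entry for (%s, %s)", target, tissue))
  if (mode == "activity") {
    e[idx, c("EM/T", "PM/T", "IM/T", "UM/T")] <-
      e[idx, c("EM/T", "PM/T", "IM/T", "UM/T")] * multiplier
  } else {
    e$abundance[idx] <- e$abundance[idx] * multiplier
  }
  new("DMETProfile", entries = e, label = label)
}

#' Final ESRD enzyme/transporter profile
#'
#' The calibrated ESRD profile: relative to healthy volunteers, hepatic
#' OATP1B1/3 activity is reduced by 75\% (x0.25, applied synchronously to
#' both), jejunal P-gp activity by 34\% (x0.66), renal OAT3 secretory
#' function scaled to the eGFR-based fraction at the population mean eGFR
#' of 10.81 mL/min/1.73 m^2 (x0.246), and ileum BCRP relative abundance is
#' doubled (0.78 -> 1.56). Hepatic and gut CYP3A4 are unchanged.
#'
#' @param multipliers named list overriding the default multipliers; names
#'   are "OATP1B", "P-gp.jejunum", "BCRP.ileum", "OAT3.renal",
#'   "CYP3A4.liver"
#' @return a [DMETProfile-class] labelled "ESRD"
#' @export
esrdDmetProfile <- function(multipliers = list()) {
  m <- list(`OATP1B` = 0.25, `P-gp.jejunum` = 0.66, `BCRP.ileum` = 2.0,
            `OAT3.renal` = 0.246, `CYP3A4.liver` = 1.0)
  m[names(multipliers)] <- multipliers
  p <- hvDmetProfile()
  p <- applyAbundanceMultiplier(p, "OATP1B", "liver", m$`OATP1B`, "activity")
  p <- applyAbundanceMultiplier(p, "P-gp", "jejunum", m$`P-gp.jejunum`, "activity")
  p <- applyAbundanceMultiplier(p, "BCRP", "ileum", m$`BCRP.ileum`, "abundance")
  p <- applyAbundanceMultiplier(p, "OAT3", "renal", m$`OAT3.renal`, "activity")
  p <- applyAbundanceMultiplier(p, "CYP3A4", "liver", m$`CYP3A4.liver`, "activity")
  p@label <- "ESRD"
  p
}

#' Look up one profile entry
#' @param profile a [DMETProfile-class]
#' @param target,tissue entry key
#' @return one-row data.frame
#' @export
profileEntry <- function(profile, target, tissue) {
  e <- profile@entries
  row <- e[e$target == target & e$tissue == tissue, , drop = FALSE]
  if (nrow(row) != 1) stop(sprintf("no profile entry for (%s, %s)", target, tissue))
  row
}

#' Effective scaled intrinsic clearance for one pathway
#'
#' The pathway building block of the simulator:
#' `clint x abundance x activity(phenotype) x inhibition`, with renal OAT3
#' additionally scaled by the individual's fractional OAT-mediated
#' secretory function. Competitive inhibition contributes
#' `1 / (1 + Iu/Ki)`; mechanism-based inactivation contributes the
#' steady-state enzyme-amount attenuation
#' `kdeg / (kdeg + kinact x Iu / (KI + Iu))`.
#'
#' @param drug a [DrugModel-class] whose `clint` holds "TARGET.tissue" keys
#' @param target,tissue pathway key; must be present in both the drug and
#'   the profile
#' @param profile a [DMETProfile-class]
#' @param individual a [VirtualIndividual-class] (phenotype and OAT3
#'   fraction)
#' @param inhibitor optional [InhibitorExposure-class]
#' @return scaled intrinsic clearance, in the drug's clint units (uL/min
#'   per abundance unit times abundance)
#' @export
effectiveClint <- function(drug, target, tissue, profile, individual,
                           inhibitor = NULL) {
  key <- paste0(target, ".", tissue)
  if (is.null(drug@clint[[key]])) stop(sprintf("drug '%s' has no clint for %s", drug@name, key))
  row <- profileEntry(profile, target, tissue)
  phen <- individual@phenotypes[[target]]
  if (is.null(phen) || is.na(phen)) phen <- "EM/T"
  act <- row[[phen]]
  x <- drug@clint[[key]] * row$abundance * act * inhibitionFactor(inhibitor, target)
  if (target == "OAT3") x <- x * individual@oat3_fraction
  x
}

#' Inhibition factor for one target
#'
#' @param inhibitor an [InhibitorExposure-class] or NULL
#' @param target target name
#' @return multiplicative factor in (0, 1]
#' @export
inhibitionFactor <- function(inhibitor, target) {
  if (is.null(inhibitor)) return(1)
  f <- 1
  if (target %in% names(inhibitor@ki))
    f <- f / (1 + inhibitor@iu / inhibitor@ki[[target]])
  if (target %in% names(inhibitor@mbi)) {
    m <- inhibitor@mbi[[target]]
    f <- f * inhibitor@kdeg /
      (inhibitor@kdeg + m$kinact * inhibitor@iu / (m$KI + inhibitor@iu))
  }
  f
}
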