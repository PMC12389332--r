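#' Synthetic study specification
#'
#' Describes the synthetic microdose-cocktail study generator: cohort size,
#' proportional residual error on observed-like concentrations, the
#' covariate model with planted linear effects on the true clearance
#' ratio, and the marginal lognormal models for genus abundances and
#' liver-function labs. The two planted genera share a community factor
#' (latent-normal correlation `w`), as co-varying gut genera do; nuisance
#' covariates are independent.
#'
#' @param n_subjects cohort size (default 10, the ESRD microdose cohort)
#' @param residual_error_cv proportional residual error on concentrations,
#'   percent (default 20, typical of microdose bioanalysis)
#' @param intercept true ratio intercept
#' @param planted named numeric of true covariate slopes
#' @param noise_cv ratio noise CV, percent of the mean true ratio
#' @param microbiome data.frame: genus, meanlog, sdlog, w (community
#'   loading in [0,1])
#' @param labs data.frame: lab, mean, cv
#' @return list of class "SyntheticStudySpec"
#' @export
syntheticStudySpec <- function(n_subjects = 10, residual_error_cv = 20,
                               intercept = 1.11,
                               planted = c(Clostridium_XVIII = 0.152,
                                           Escherichia = 0.0558),
                               noise_cv = 2,
                               microbiome = data.frame(
                                 genus = c("Clostridium_XVIII", "Escherichia",
                                           "Bacteroides", "Megamonas"),
                                 meanlog = log(c(2, 5.7, 20, 1)),
                                 sdlog = c(0.4, 0.4, 0.5, 0.6),
                                 w = c(0.8, 0.8, 0, 0)),
                               labs = data.frame(
                                 lab = c("AST", "TBIL", "ALT"),
                                 mean = c(22, 9, 20),
                                 cv = c(30, 35, 40))) {
  stopifnot(n_subjects >= 1, residual_error_cv >= 0, noise_cv >= 0)
  structure(list(n_subjects = n_subjects,
                 residual_error_cv = residual_error_cv,
                 intercept = intercept, planted = planted,
                 noise_cv = noise_cv, microbiome = microbiome, labs = labs),
            class = "SyntheticStudySpec")
}

#' Generate a synthetic covariate table with planted effects
#'
#' Genus relative abundances are marginally lognormal with an optional
#' shared community factor; labs are lognormal. The true per-subject
#' clearance ratio is `intercept + sum(planted slope x covariate)` plus
#' normal noise.
#'
#' @param spec a [syntheticStudySpec()]
#' @param seed integer seed
#' @return list: `covariates` (data.frame, one row per subject),
#'   `true_ratio` (numeric), `spec`
#' @export
genCohortCovariates <- function(spec = syntheticStudySpec(), seed = 1) {
  withSeed(seed, {
    n <- spec$n_subjects
    z_comm <- rnorm(n)
    mb <- spec$microbiome
    cov <- data.frame(subject = seq_len(n))
    for (i in seq_len(nrow(mb))) {
      w <- mb$w[i]
      z <- sqrt(w) * z_comm + sqrt(1 - w) * rnorm(n)
      cov[[mb$genus[i]]] <- exp(mb$meanlog[i] + mb$sdlog[i] * z)
    }
    for (i in seq_len(nrow(spec$labs)))
      cov[[spec$labs$lab[i]]] <- rlnormMeanCV(n, spec$labs$mean[i], spec$labs$cv[i])
    true <- rep(spec$intercept, n)
    for (nm in names(spec$planted)) {
      if (is.null(cov[[nm]])) stop(sprintf("planted covariate '%s' not generated", nm))
      true <- true + spec$planted[[nm]] * cov[[nm]]
    }
    if (spec$noise_cv > 0)
      true <- true + rnorm(n, 0, spec$noise_cv / 100 * mean(true))
    list(covariates = cov, true_ratio = true, spec = spec)
  })
}

#' Generate observed-like concentration tables
#'
#' Simulates each cohort subject under the drug model and multiplies each
#' sampled concentration by lognormal proportional residual error
#' (mean-one parameterisation), emulating bioanalytical noise.
#'
#' @param drug a [DrugModel-class]
#' @param cohort list of [VirtualIndividual-class]
#' @param regimen a [DoseRegimen-class]
#' @param profile a [DMETProfile-class]
#' @param sample_times sampling schedule, h (includes the predose sample
#'   so downstream AUCs cover the full profile)
#' @param residual_cv proportional error, percent
#' @param seed integer seed
#' @return tidy data.frame: subject, time_h, conc (mg/L)
#' @export
genObservedPK <- function(drug, cohort, regimen, profile,
                          sample_times = c(0, 0.25, 0.5, 1, 1.5, 2, 3, 4, 6,
                                           8, 12, 24, 36, 48, 72),
                          residual_cv = 20, seed = 1) {
  if (residual_cv < 0) stop("residual_cv must be non-negative")
  sdlog <- sqrt(log(1 + (residual_cv / 100)^2))
  withSeed(seed, {
    out <- lapply(seq_along(cohort), function(i) {
      sim <- simulateDrug(drug, regimen, cohort[[i]], profile,
                          t_end = max(sample_times))
      conc <- vapply(sample_times, function(tt)
        sim@conc$plasma[which.min(abs(sim@t - tt))], numeric(1))
      err <- if (residual_cv > 0)
        rlnorm(length(conc), -sdlog^2 / 2, sdlog) else rep(1, length(conc))
      data.frame(subject = i, time_h = sample_times, conc = conc * err)
    })
    do.call(rbind, out)
  })
}

## ---- structured-text (YAML) fixture serialisation ----

.drugToList <- function(d) {
  list(name = d@name, mw = d@mw, fu_hv = d@fu_hv,
       fu_esrd_ratio = d@fu_esrd_ratio, binding_protein = d@binding_protein,
       blood_plasma_ratio = d@blood_plasma_ratio, ka = d@ka,
       colon_ka_factor = d@colon_ka_factor, vss = d@vss,
       kp_muscle = d@kp_muscle, ps_liver = d@ps_liver, clint = d@clint,
       cl_met_other = d@cl_met_other, cl_extra = d@cl_extra,
       renal_filtration = d@renal_filtration,
       prodrug_conversion_k = d@prodrug_conversion_k)
}

#' Write / read a drug model as YAML
#' @param drug a [DrugModel-class]
#' @param path file path
#' @return `readDrugModel` returns a [DrugModel-class]
#' @export
writeDrugModel <- function(drug, path) {
  yaml::write_yaml(.drugToList(drug), path, precision = 15)
  invisible(path)
}

#' @rdname writeDrugModel
#' @export
readDrugModel <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(drugModel, x)
}

#' Write / read an inhibitor exposure as YAML
#' @param inhibitor an [InhibitorExposure-class]
#' @param path file path
#' @return `readInhibitor` returns an [InhibitorExposure-class]
#' @export
writeInhibitor <- function(inhibitor, path) {
  yaml::write_yaml(list(name = inhibitor@name, iu = inhibitor@iu,
                        ki = as.list(inhibitor@ki), mbi = inhibitor@mbi,
                        kdeg = inhibitor@kdeg), path, precision = 15)
  invisible(path)
}

#' @rdname writeInhibitor
#' @export
readInhibitor <- function(path) {
  x <- yaml::read_yaml(path)
  new("InhibitorExposure", name = x$name, iu = x$iu,
      ki = unlist(x$ki %||% list()) %||% setNames(numeric(0), character(0)),
      mbi = x$mbi %||% list(), kdeg = x$kdeg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read an abundance profile as YAML
#' @param profile a [DMETProfile-class]
#' @param path file path
#' @return `readDmetProfile` returns a [DMETProfile-class]
#' @export
writeDmetProfile <- function(profile, path) {
  e <- profile@entries
  rows <- lapply(seq_len(nrow(e)), function(i) as.list(e[i, ]))
  yaml::write_yaml(list(label = profile@label, entries = rows), path,
                   precision = 15)
  invisible(path)
}

#' @rdname writeDmetProfile
#' @export
readDmetProfile <- function(path) {
  x <- yaml::read_yaml(path)
  e <- do.call(rbind, lapply(x$entries, function(r)
    data.frame(r, check.names = FALSE)))
  new("DMETProfile", entries = e, label = x$label)
}

.specToList <- function(s) {
  df2rows <- function(d) lapply(seq_len(nrow(d)), function(i) as.list(d[i, ]))
  list(label = s@label,
       height = s@demographics@height, weight = s@demographics@weight,
       creatinine = df2rows(s@creatinine), blood = df2rows(s@blood),
       kidney = as.list(s@kidney), gi = as.list(s@gi),
       phenotype_freq = lapply(s@phenotype_freq, as.list),
       age_range = s@age_range, female_fraction = s@female_fraction,
       height_cv = s@height_cv, weight_cv = s@weight_cv)
}

#' Write / read a population spec as YAML
#' @param spec a [PopulationSpec-class]
#' @param path file path
#' @return `readPopulationSpec` returns a [PopulationSpec-class]
#' @export
writePopulationSpec <- function(spec, path) {
  yaml::write_yaml(.specToList(spec), path, precision = 15)
  invisible(path)
}

#' @rdname writePopulationSpec
#' @export
readPopulationSpec <- function(path) {
  x <- yaml::read_yaml(path)
  rows2df <- function(rows) do.call(rbind, lapply(rows, function(r)
    data.frame(r, check.names = FALSE)))
  cr <- rows2df(x$creatinine)
  cr$hi <- as.numeric(cr$hi) # ".inf" round-trips as Inf
  new("PopulationSpec", label = x$label,
      demographics = new("DemographicModel",
                         height = lapply(x$height, unlist),
                         weight = lapply(x$weight, unlist)),
      creatinine = cr, blood = rows2df(x$blood),
      kidney = unlist(x$kidney), gi = unlist(x$gi),
      phenotype_freq = lapply(x$phenotype_freq, unlist),
      age_range = unlist(x$age_range), female_fraction = x$female_fraction,
      height_cv = x$height_cv, weight_cv = x$weight_cv)
}

#' Write every fixture file
#'
#' Writes the five probe-drug models, the five perpetrator models, the
#' healthy-volunteer and ESRD population specs, and the healthy-volunteer
#' and final ESRD abundance profiles as YAML under `out_dir`.
#'
#' @param out_dir writable directory (created if absent)
#' @return invisible character vector of written paths
#' @export
makeFixtures <- function(out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in c("midazolam", "dabigatran", "pitavastatin", "rosuvastatin",
               "atorvastatin"))
    paths <- c(paths, writeDrugModel(drugFixture(nm),
                                     file.path(out_dir, paste0("drug_", nm, ".yaml"))))
  for (nm in c("rifampin", "itraconazole", "clarithromycin", "ritonavir",
               "verapamil"))
    paths <- c(paths, writeInhibitor(inhibitorFixture(nm),
                                     file.path(out_dir, paste0("inhibitor_", nm, ".yaml"))))
  paths <- c(paths,
             writePopulationSpec(hvPopulationSpec(), file.path(out_dir, "population_hv.yaml")),
             writePopulationSpec(esrdPopulationSpec(), file.path(out_dir, "population_esrd.yaml")),
             writeDmetProfile(hvDmetProfile(), file.path(out_dir, "dmet_hv.yaml")),
             writeDmetProfile(esrdDmetProfile(), file.path(out_dir, "dmet_esrd.yaml")))
  invisible(paths)
}
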