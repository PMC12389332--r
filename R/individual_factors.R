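#' PBPK/reference apparent-clearance ratio
#'
#' @param cl_pbpk PBPK-predicted apparent clearance, L/h
#' @param cl_ppk reference (population-PK) apparent clearance, L/h
#' @return cl_pbpk / cl_ppk
#' @export
clfRatio <- function(cl_pbpk, cl_ppk) {
  if (any(cl_pbpk <= 0) || any(cl_ppk <= 0)) stop("clearances must be positive")
  cl_pbpk / cl_ppk
}

#' Correlation screen of candidate covariates
#'
#' Correlates each covariate column against the clearance ratio and
#' retains those with p < alpha. Spearman by default (robust at the small
#' sample sizes of microdose-cocktail cohorts); Pearson selectable.
#' Zero-variance covariates are excluded with a warning.
#'
#' @param table data.frame of covariates (one row per subject; a `subject`
#'   column, if present, is ignored)
#' @param ratios numeric vector of CL/F ratios, one per row
#' @param alpha significance threshold (default 0.05)
#' @param method "spearman" or "pearson"
#' @return data.frame: covariate, estimate, p_value, retained
#' @export
correlationScreen <- function(table, ratios, alpha = 0.05,
                              method = c("spearman", "pearson")) {
  method <- match.arg(method)
  table <- table[setdiff(names(table), "subject")]
  if (nrow(table) < 4) stop("need at least 4 subjects")
  if (nrow(table) != length(ratios)) stop("one ratio per subject required")
  rows <- lapply(names(table), function(nm) {
    x <- table[[nm]]
    if (sd(x) == 0) {
      warning(sprintf("covariate '%s' has zero variance; excluded", nm))
      return(data.frame(covariate = nm, estimate = NA_real_,
                        p_value = NA_real_, retained = FALSE))
    }
    ct <- suppressWarnings(cor.test(x, ratios, method = method, exact = NULL))
    data.frame(covariate = nm, estimate = unname(ct$estimate),
               p_value = ct$p.value, retained = ct$p.value < alpha)
  })
  do.call(rbind, rows)
}

#' LASSO covariate selection with OLS refit
#'
#' Fits the LASSO path (glmnet, internally standardised), chooses lambda
#' by cross-validated error at the minimum (lambda.min; leave-one-out
#' folds when n <= 12, else 10-fold), and refits the covariates with
#' non-zero coefficients by ordinary least squares on the raw covariate
#' scales to produce the final unshrunken correction equation.
#' Perfectly collinear duplicates among the selected set are dropped in
#' column order during the refit (the OLS fit leaves them undetermined).
#'
#' @param X data.frame or matrix of screened covariates
#' @param y clearance ratios
#' @param drug drug label for the resulting equation
#' @param seed integer seed for fold assignment
#' @param cv_folds optional fold count override
#' @return list: `equation` (a [CorrectionEquation-class]), `selected`
#'   (character vector), `lambda_min`, `cvm_min`
#' @export
lassoSelect <- function(X, y, drug = "drug", seed = 1, cv_folds = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (is.null(cv_folds)) cv_folds <- if (n <= 12) n else 10
  if (n < cv_folds || cv_folds < 2) stop("need n >= folds >= 2")
  if (sd(y) == 0 || ncol(X) == 0 || all(apply(X, 2, sd) == 0)) {
    return(list(equation = new("CorrectionEquation", drug = drug,
                               intercept = mean(y),
                               coefficients = setNames(numeric(0), character(0))),
                selected = character(0), lambda_min = NA_real_,
                cvm_min = NA_real_))
  }
  # glmnet requires >= 2 columns; pad a single screened covariate with an
  # inert zero column (its coefficient is identically 0 and never selected)
  Xfit <- if (ncol(X) == 1) cbind(X, `..pad..` = 0) else X
  cv <- withSeed(seed, {
    foldid <- sample(rep_len(seq_len(cv_folds), n))
    glmnet::cv.glmnet(Xfit, y, alpha = 1, foldid = foldid, standardize = TRUE,
                      grouped = FALSE)
  })
  beta <- coef(cv, s = "lambda.min")[-1, 1]
  selected <- setdiff(names(beta)[beta != 0], "..pad..")
  if (!length(selected)) {
    eq <- new("CorrectionEquation", drug = drug, intercept = mean(y),
              coefficients = setNames(numeric(0), character(0)))
    return(list(equation = eq, selected = character(0),
                lambda_min = cv$lambda.min, cvm_min = min(cv$cvm)))
  }
  df <- data.frame(y = y, X[, selected, drop = FALSE], check.names = FALSE)
  fit <- lm(y ~ ., data = df)
  cf <- coef(fit)
  keep <- !is.na(cf)
  cf <- cf[keep]
  coefs <- cf[-1]
  names(coefs) <- sub("^`|`$", "", names(coefs))
  eq <- new("CorrectionEquation", drug = drug, intercept = unname(cf[1]),
            coefficients = coefs)
  list(equation = eq, selected = names(coefs), lambda_min = cv$lambda.min,
       cvm_min = min(cv$cvm))
}

#' Apply a correction equation to PBPK clearances
#'
#' Predicts the CL/F ratio (`intercept + sum(coef x covariate)`) for each
#' subject and divides the PBPK clearance by it, so the corrected value
#' approximates the reference clearance. Subjects with a non-positive
#' predicted ratio are flagged and left uncorrected (NA).
#'
#' @param eq a [CorrectionEquation-class]
#' @param covariates data.frame with the equation's covariate columns
#' @param cl_pbpk PBPK-predicted clearances, one per row
#' @return data.frame: ratio_pred, cl_corrected, flagged
#' @export
applyCorrection <- function(eq, covariates, cl_pbpk) {
  missing <- setdiff(names(eq@coefficients), names(covariates))
  if (length(missing))
    stop(sprintf("missing covariate(s): %s", paste(missing, collapse = ", ")))
  ratio <- rep(eq@intercept, max(nrow(covariates), length(cl_pbpk)))
  for (nm in names(eq@coefficients))
    ratio <- ratio + eq@coefficients[[nm]] * covariates[[nm]]
  flagged <- ratio <= 0
  corrected <- ifelse(flagged, NA_real_, cl_pbpk / ratio)
  data.frame(ratio_pred = ratio, cl_corrected = corrected, flagged = flagged)
}

#' Full individual-factor selection pipeline
#'
#' Correlation screen at `alpha`, LASSO at lambda.min over the retained
#' covariates, OLS refit, and a before/after comparison of the agreement
#' (R^2) between PBPK-predicted and reference clearance.
#'
#' @param covariates covariate table (one row per subject)
#' @param cl_pbpk,cl_ppk per-subject clearances
#' @param drug drug label
#' @param alpha screen threshold
#' @param method correlation method
#' @param seed seed for CV folds
#' @return list: `screen`, `equation`, `selected`, `lambda_min`,
#'   `r2_before`, `r2_after`, `corrected` (per-subject table)
#' @export
selectIndividualFactors <- function(covariates, cl_pbpk, cl_ppk,
                                    drug = "drug", alpha = 0.05,
                                    method = "spearman", seed = 1) {
  ratios <- clfRatio(cl_pbpk, cl_ppk)
  screen <- correlationScreen(covariates, ratios, alpha = alpha, method = method)
  kept <- screen$covariate[screen$retained]
  sel <- lassoSelect(covariates[, kept, drop = FALSE], ratios, drug = drug,
                     seed = seed)
  corr <- applyCorrection(sel$equation, covariates, cl_pbpk)
  r2 <- function(pred, ref) {
    ok <- is.finite(pred) & is.finite(ref)
    if (sum(ok) < 3 || sd(pred[ok]) == 0) return(NA_real_)
    stats::cor(pred[ok], ref[ok])^2
  }
  list(screen = screen, equation = sel$equation, selected = sel$selected,
       lambda_min = sel$lambda_min,
       r2_before = r2(cl_pbpk, cl_ppk),
       r2_after = r2(corr$cl_corrected, cl_ppk),
       corrected = corr)
}

#' Published dabigatran correction equation
#'
#' CL/F ratio for dabigatran as a function of gut-microbiome genus
#' relative abundances:
#' `1.11 + 0.152 x Clostridium_XVIII + 0.0558 x Escherichia`.
#'
#' @return a [CorrectionEquation-class]
#' @export
dabCorrectionEquation <- function() {
  new("CorrectionEquation", drug = "dabigatran", intercept = 1.11,
      coefficients = c(Clostridium_XVIII = 0.152, Escherichia = 0.0558))
}

#' Published rosuvastatin correction equation
#'
#' CL/F ratio for rosuvastatin from liver-function labs and genus
#' abundances:
#' `1.67 - 0.0581 x AST + 0.0347 x TBIL - 0.00596 x Bacteroides +
#'  1.847 x Megamonas` (AST in U/L, TBIL in umol/L).
#'
#' @return a [CorrectionEquation-class]
#' @export
rsvCorrectionEquation <- function() {
  new("CorrectionEquation", drug = "rosuvastatin", intercept = 1.67,
      coefficients = c(AST = -0.0581, TBIL = 0.0347, Bacteroides = -0.00596,
                       Megamonas = 1.847))
}

#' Evaluate a correction equation at covariate values
#'
#' @param eq a [CorrectionEquation-class]
#' @param ... named covariate values (unnamed covariates default to 0)
#' @return predicted CL/F ratio
#' @export
evaluateEquation <- function(eq, ...) {
  vals <- list(...)
  r <- eq@intercept
  for (nm in names(eq@coefficients))
    r <- r + eq@coefficients[[nm]] * (if (!is.null(vals[[nm]])) vals[[nm]] else 0)
  r
}
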