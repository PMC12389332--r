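test_that("clearance ratio arithmetic and domain errors", {
  expect_equal(clfRatio(2, 2), 1)
  expect_equal(clfRatio(3, 2), 1.5)
  expect_error(clfRatio(2, 0), "positive")
})

test_that("correlation screen keeps perfect predictors and drops constants", {
  ratios <- c(1.2, 0.8, 1.5, 1.1, 0.9, 1.3, 1.0, 1.4, 0.7, 1.6)
  tab <- data.frame(perfect = ratios, constant = rep(2, 10))
  expect_warning(res <- correlationScreen(tab, ratios), "zero variance")
  expect_true(res$retained[res$covariate == "perfect"])
  expect_equal(res$estimate[res$covariate == "perfect"], 1)
  expect_false(res$retained[res$covariate == "constant"])
  expect_error(correlationScreen(tab[1:3, ], ratios[1:3]), "4 subjects")
})

test_that("null covariates are retained at roughly the nominal alpha", {
  ratios <- esrdpbpk:::withSeed(31, rnorm(10))
  hits <- esrdpbpk:::withSeed(32, {
    vapply(1:400, function(i) {
      tab <- data.frame(x = sample(ratios))
      correlationScreen(tab, ratios)$retained
    }, logical(1))
  })
  expect_gt(mean(hits), 0.005)
  expect_lt(mean(hits), 0.12)
})

test_that("LASSO selects a planted effect and refits it without shrinkage", {
  gen <- esrdpbpk:::withSeed(2, {
    x1 <- rlnorm(10, 0, 0.5)
    x2 <- rlnorm(10, 0, 0.5)
    y <- 1.1 + 0.5 * x1
    y <- y + rnorm(10, 0, 0.02 * mean(y))
    list(X = data.frame(x1 = x1, x2 = x2), y = y)
  })
  sel <- lassoSelect(gen$X, gen$y, seed = 2)
  expect_identical(sel$selected, "x1")
  expect_equal(unname(sel$equation@coefficients[["x1"]]), 0.5, tolerance = 0.1)
  expect_false(is.na(sel$lambda_min))
})

test_that("degenerate designs collapse to intercept-only equations", {
  y <- rep(1.4, 10)
  sel <- lassoSelect(data.frame(x = rnorm(10)), y, seed = 1)
  expect_length(sel$selected, 0)
  expect_equal(sel$equation@intercept, 1.4)
  sel0 <- lassoSelect(data.frame(x = rep(1, 10)), seq(0.5, 1.4, by = 0.1), seed = 1)
  expect_length(sel0$selected, 0)
})

test_that("duplicated covariate columns resolve to a single refit term", {
  gen <- esrdpbpk:::withSeed(13, {
    x <- rlnorm(10, 0, 0.5)
    y <- 1 + 0.5 * x + rnorm(10, 0, 0.01)
    data.frame(a = x, b = x, y = y)
  })
  sel <- lassoSelect(gen[c("a", "b")], gen$y, seed = 13)
  expect_gte(length(sel$selected), 1)
  expect_true(all(is.finite(sel$equation@coefficients)))
  pred <- applyCorrection(sel$equation, gen[c("a", "b")], rep(1, 10))
  expect_equal(pred$ratio_pred, gen$y, tolerance = 0.05)
})

test_that("published correction equations evaluate at their printed anchors", {
  eq1 <- dabCorrectionEquation()
  expect_equal(evaluateEquation(eq1), 1.11)
  expect_equal(evaluateEquation(eq1, Clostridium_XVIII = 1, Escherichia = 1),
               1.11 + 0.152 + 0.0558, tolerance = 1e-12)
  eq2 <- rsvCorrectionEquation()
  expect_equal(evaluateEquation(eq2), 1.67)
  expect_equal(evaluateEquation(eq2, AST = 10, TBIL = 5, Bacteroides = 20,
                                Megamonas = 0.5),
               1.67 - 0.581 + 0.1735 - 0.1192 + 0.9235, tolerance = 1e-9)
})

test_that("applying a correction divides by the predicted ratio exactly", {
  eq <- new("CorrectionEquation", drug = "d", intercept = 1.2,
            coefficients = c(u = 0.3, v = -0.1))
  cov <- data.frame(u = c(0, 1, 2), v = c(0, 2, 10))
  out <- applyCorrection(eq, cov, cl_pbpk = c(10, 10, 10))
  manual <- 1.2 + 0.3 * cov$u - 0.1 * cov$v
  expect_equal(out$ratio_pred, manual)
  expect_equal(out$cl_corrected, 10 / manual)
  expect_false(any(out$flagged))
})

test_that("non-positive predicted ratios are flagged, missing covariates error", {
  eq <- new("CorrectionEquation", drug = "d", intercept = 0.1,
            coefficients = c(u = -1))
  out <- applyCorrection(eq, data.frame(u = c(0, 1)), c(5, 5))
  expect_false(out$flagged[1])
  expect_true(out$flagged[2])
  expect_true(is.na(out$cl_corrected[2]))
  expect_error(applyCorrection(eq, data.frame(z = 1), 5), "missing covariate")
})

test_that("planted two-covariate effects are recovered in >= 90% of replicates", {
  spec <- recoveryStudySpec()
  planted <- c("Clostridium_XVIII", "Escherichia")
  hits <- 0
  coefs <- NULL
  for (s in 1:100) {
    gen <- genCohortCovariates(spec, seed = s)
    cl_ppk <- 2 * rep(1, spec$n_subjects)
    cl_pbpk <- cl_ppk * gen$true_ratio
    sel <- suppressWarnings(
      selectIndividualFactors(gen$covariates, cl_pbpk, cl_ppk, seed = s))
    if (setequal(sel$selected, planted)) {
      hits <- hits + 1
      coefs <- rbind(coefs, sel$equation@coefficients[planted])
    }
  }
  expect_gte(hits, 90)
  expect_equal(unname(colMeans(coefs)), c(0.152, 0.0558), tolerance = 0.15)
})

test_that("the fitted correction strictly improves agreement with the reference", {
  gen <- genCohortCovariates(recoveryStudySpec(), seed = 5)
  cl_ppk <- esrdpbpk:::withSeed(6, 8 * rlnormMeanCV(10, 1, 25))
  cl_pbpk <- cl_ppk * gen$true_ratio
  sel <- suppressWarnings(
    selectIndividualFactors(gen$covariates, cl_pbpk, cl_ppk, seed = 5))
  expect_gt(sel$r2_after, sel$r2_before)
  expect_gt(sel$r2_after, 0.95)
})
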