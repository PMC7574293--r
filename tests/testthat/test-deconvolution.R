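# Box-constrained least-squares deconvolution: design construction, the QP
# solver against closed-form and grid oracles, SEs, group-level recovery.

test_that("buildDesign renormalizes after exclusion and pools minors", {
  cc <- data.frame(sample_id = "A1", group = "asthma",
                   AM = 27.9, NG = 54.7, EO = 12.9, LY = 0.7, MO = 0.1,
                   CC = 1.6, SC = 2.1)
  d <- buildDesign(cc, c("AM", "NG", "EO"), excluded = "MO")
  row <- designMatrix(d)[1, ]
  expect_equal(unname(row),
               c(27.9, 54.7, 12.9, 0.7 + 1.6 + 2.1) / 99.9,
               tolerance = 1e-10)
  expect_equal(sum(row), 1, tolerance = 1e-12)
  expect_identical(majorTypes(d), c("AM", "NG", "EO"))

  pure <- data.frame(AM = 100, NG = 0, EO = 0, LY = 0, MO = 0, CC = 0,
                     SC = 0)
  expect_equal(unname(designMatrix(buildDesign(pure, c("AM", "NG", "EO")))[1, ]),
               c(1, 0, 0, 0))
  eq <- data.frame(AM = 100 / 3, NG = 100 / 3, EO = 100 / 3)
  expect_equal(unname(designMatrix(buildDesign(eq, c("AM", "NG", "EO"),
                                               excluded = character(0)))[1, ]),
               c(1 / 3, 1 / 3, 1 / 3, 0), tolerance = 1e-10)
  expect_error(buildDesign(cc, c("AM", "XX")), "absent")
  expect_error(buildDesign(data.frame(AM = 50, NG = 20), "AM"), "100")
})

test_that("solveBoxLS matches trivial and noiseless solutions", {
  s <- solveBoxLS(diag(2), c(0.5, 1.2), 0, 1)
  expect_equal(unname(s$beta), c(0.5, 1.0), tolerance = 1e-10)
  expect_equal(sum(s$active != 0), 1L)

  F <- rbind(c(0.3, 0.7), c(0.6, 0.4), c(0.5, 0.5))
  y <- c(0.62, 0.44, 0.50)
  s2 <- solveBoxLS(F, y, 0, 1)
  expect_equal(unname(s2$beta), c(0.2, 0.8), tolerance = 1e-6)
  expect_error(solveBoxLS(diag(2), c(1, 1), 1, 0), "infeasible")
})

test_that("interior solutions equal closed-form OLS on 1000 random instances", {
  set.seed(41)
  n <- 0
  while (n < 1000) {
    F <- matrix(runif(10, 0.1, 0.9), 5, 2)
    y <- as.vector(F %*% runif(2, 0.2, 0.8)) + rnorm(5, 0, 0.02)
    ols <- qr.solve(F, y)  # independent least-squares route
    if (all(ols > 0 & ols < 1)) {
      n <- n + 1
      qp <- solveBoxLS(F, y, 0, 1)
      expect_lt(max(abs(qp$beta - ols)), 1e-8)
    }
  }
})

test_that("constrained solutions beat a fine grid on 200 exterior instances", {
  set.seed(42)
  n <- 0
  while (n < 200) {
    F <- matrix(runif(10, 0.1, 0.9), 5, 2)
    y <- as.vector(F %*% runif(2, -0.5, 1.5)) + rnorm(5, 0, 0.1)
    ols <- qr.solve(F, y)
    if (any(ols < 0 | ols > 1)) {
      n <- n + 1
      sol <- solveBoxLS(F, y, 0, 1)
      expect_true(all(sol$beta >= 0 & sol$beta <= 1))
      expect_lte(sol$objective, gridOracleMin(F, y) + 1e-9)
    }
  }
})

test_that("standard errors follow the closed-form regression formula", {
  # zero residuals -> all SEs zero
  F <- cbind(1, c(0.1, 0.4, 0.7, 0.9))
  y <- as.vector(F %*% c(0.2, 0.5))
  se0 <- estimateSEs(F, y - as.vector(F %*% qr.solve(F, y)))
  expect_equal(unname(se0$se[1, ]), c(0, 0), tolerance = 1e-12)
  expect_equal(se0$df, 2)

  # orthonormal design: every SE equals sigma-hat
  Fo <- qr.Q(qr(matrix(rnorm(10), 5, 2)))
  resid <- c(1, -1, 1, -1, 1) * 0.3
  s <- sqrt(sum(resid^2) / 3)
  seo <- estimateSEs(Fo, resid)
  expect_equal(unname(seo$se[1, ]), rep(s, 2), tolerance = 1e-12)

  # random instance vs an independent lm() fit
  set.seed(43)
  Fr <- cbind(1, runif(8), runif(8))
  yr <- rnorm(8)
  fit <- lm(yr ~ Fr - 1)
  ser <- estimateSEs(Fr, fit$residuals)
  expect_equal(unname(ser$se[1, ]),
               unname(summary(fit)$coefficients[, "Std. Error"]),
               tolerance = 1e-10)
  expect_error(estimateSEs(Fr[1:3, ], rnorm(3)), "degrees of freedom")
})

test_that("noiseless group deconvolution recovers planted profiles exactly", {
  p <- generateProfiles(150, profileConfig(nDegPerGroup = 0,
                                           nDmpPerGroup = 0), seed = 51)
  fr <- generateCellFractions("asthma", 10, seed = 52)
  mx <- mixProfiles(p, fr, noiseSd = c(expression = 0, methylation = 0))
  d <- buildDesign(fr, c("AM", "NG", "EO"))
  est <- deconvolveGroup(mx$methylation, d, group = "asthma")
  # the design pools LY/CC/SC into "other" and drops MO, so compare the
  # major columns only, on features where the planted betas are interior
  truth <- t(p$methylation$asthma[c("AM", "NG", "EO"), ])
  err <- abs(estimates(est)[, c("AM", "NG", "EO")] - truth)
  interior <- rowSums(truth <= 0.02 | truth >= 0.98) == 0
  # MO carries profile signal not in the design; its fraction is ~0.1% so
  # the residual contamination is bounded by that scale
  expect_lt(max(err[interior & est@nActive == 0, ]), 0.05)
  expect_equal(unname(residualDf(est)[1]), 6)
})

test_that("deconvolution is scale-guarded and respects bounds everywhere", {
  study <- cachedStudy()
  gs <- study$samples$sample_id[study$samples$group == "asthma"]
  d <- buildDesign(study$fractions[study$fractions$sample_id %in% gs, ],
                   c("AM", "NG", "EO"))
  log2moe <- MixedOmicsExperiment(
    log2(pmax(omicsMatrix(study$expressionClean[, gs]), 1)),
    "expression-log2"
  )
  expect_error(deconvolveGroup(log2moe, d), "linear")

  est <- deconvolveGroup(study$methylation[, gs], d, group = "asthma")
  expect_true(all(estimates(est) >= 0 & estimates(est) <= 1, na.rm = TRUE))
  expect_true(all(standardErrors(est) >= 0, na.rm = TRUE))
  lin <- study$expressionClean[, gs]
  estE <- deconvolveGroup(lin, d, group = "asthma")
  b <- resolveBounds(lin, "auto")
  expect_true(all(estimates(estE) >= b[1] - 1e-8 &
                    estimates(estE) <= b[2] + 1e-8, na.rm = TRUE))
})

test_that("noisy recovery is accurate for prevalent, variable cell types", {
  study <- cachedStudy(
    "recovery",
    function() simulateSputumStudy(sputumStudyConfig(), seed = 1)
  )
  fr <- study$fractions
  gs <- study$samples$sample_id[study$samples$group == "asthma"]
  d <- buildDesign(fr[fr$sample_id %in% gs, ], c("AM", "NG", "EO"))
  em <- deconvolveGroup(study$methylation[, gs], d, group = "asthma")
  truthM <- study$profiles$methylation$asthma
  for (ct in c("AM", "NG", "EO")) {
    expect_gt(cor(estimates(em)[, ct], truthM[ct, rownames(estimates(em))]),
              0.9)
  }
})

test_that("shrinking a cell type's fraction variance inflates its SEs monotonically", {
  study <- cachedStudy(
    "recovery",
    function() simulateSputumStudy(sputumStudyConfig(), seed = 1)
  )
  fr <- study$fractions[study$fractions$group == "asthma", ]
  ct <- study$profiles$cellTypes
  meanSE <- vapply(c(1, 0.5, 0.25, 0.1), function(f) {
    fr2 <- fr
    fr2$EO <- mean(fr$EO) + f * (fr$EO - mean(fr$EO))
    m <- as.matrix(fr2[, ct])
    fr2[, ct] <- m / rowSums(m) * 100
    mx <- mixProfiles(study$profiles, fr2, seed = 99)
    d <- buildDesign(fr2, c("AM", "NG", "EO"))
    em <- deconvolveGroup(mx$methylation, d, group = "asthma")
    mean(standardErrors(em)[, "EO"])
  }, numeric(1))
  expect_true(all(diff(meanSE) > 0))
})
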