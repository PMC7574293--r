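# Synthetic sputum-study generator: fractions, RIN, profiles, mixing,
# degradation, dataset round trips.

test_that("cell-fraction sampling respects the simplex and the group means", {
  cc <- generateCellFractions("asthma", 10000, seed = 7)
  ct <- c("AM", "NG", "EO", "LY", "MO", "CC", "SC")
  expect_true(all(abs(rowSums(cc[, ct]) - 100) < 1e-6))
  means <- colMeans(cc[, ct])
  published <- c(AM = 27.9, NG = 54.7, EO = 12.9, LY = 0.7, MO = 0.1,
                 CC = 1.6, SC = 2.1)
  expect_true(all(abs(means - published / sum(published) * 100) < 1))
})

test_that("degenerate and deterministic fraction sampling behave as stated", {
  model <- sputumFractionModel(concentration = c(asthma = Inf, copd = 21,
                                                 control = 3))
  cc <- generateCellFractions("asthma", 3, model = model, seed = 1)
  for (i in 1:3) {
    expect_equal(unlist(cc[i, -(1:2)]),
                 unlist(cc[1, -(1:2)]), tolerance = 1e-12)
  }
  a <- generateCellFractions("copd", 5, seed = 42)
  b <- generateCellFractions("copd", 5, seed = 42)
  expect_identical(a, b)
  expect_error(generateCellFractions("emphysema", 3), "unknown group")
})

test_that("RIN sampling stays inside the preservation-specific bounds", {
  rlt <- generateRIN("RLT", 1000, seed = 3)
  expect_true(all(rlt >= 7.6 & rlt <= 9.1))
  hope <- generateRIN("HOPE", 1000, seed = 3)
  expect_true(all(hope >= 3.2 & hope <= 5.1))
  m <- degradationModel(rinLaw = list(RLT = c(mean = 8, sd = 0, min = 7,
                                              max = 9)))
  expect_equal(generateRIN("RLT", 5, model = m), rep(8, 5))
  expect_error(generateRIN("formalin", 5), "unknown preservation")
})

test_that("profile truth tables record spiked effects and clipping", {
  cfg0 <- profileConfig(nDegPerGroup = 0, nDmpPerGroup = 0)
  p0 <- generateProfiles(200, cfg0, seed = 5)
  expect_equal(nrow(p0$effects), 0L)

  p <- generateProfiles(400, seed = 5)
  expect_true(all(p$methylation$control >= 0 & p$methylation$control <= 1))
  expect_true(all(p$expression$control >= p$dynRange[1L] &
                    p$expression$control <= p$dynRange[2L]))
  eff <- p$effects
  expect_true(all(c("asthma", "copd") %in% eff$group))
  # non-spiked features carry no effect: group profiles equal the baseline
  exprEff <- unique(eff$feature[eff$modality == "expression"])
  same <- setdiff(p$exprIds, exprEff)
  expect_equal(p$expression$asthma[, same], p$expression$control[, same])
  # spiked expression effects are the nominal log2FC unless clipped
  e1 <- eff[eff$modality == "expression" & !eff$clipped, ]
  expect_true(all(abs(abs(e1$achieved) - 1.5) < 1e-12))
  # clipping bookkeeping: achieved is the realized, in-bounds change
  em <- eff[eff$modality == "methylation", ]
  idx <- cbind(em$cell_type, em$feature)
  expect_equal(p$methylation$control[idx[em$group == "asthma", ]] +
                 em$achieved[em$group == "asthma"],
               p$methylation$asthma[idx[em$group == "asthma", ]],
               tolerance = 1e-12)
  expect_true(all(abs(em$achieved) <= abs(em$nominal) + 1e-12))
})

test_that("near-boundary methylation spikes are clipped with achieved effects recorded", {
  p <- generateProfiles(400, seed = 5)
  em <- p$effects[p$effects$modality == "methylation" & p$effects$clipped, ]
  expect_gt(nrow(em), 0)  # bimodal betas make boundary clips inevitable
  base <- p$methylation$control[cbind(em$cell_type, em$feature)]
  expect_equal(em$achieved,
               pmin(pmax(base + em$nominal, 0.001), 0.999) - base,
               tolerance = 1e-12)
  expect_true(all(abs(em$achieved) < abs(em$nominal)))
})

test_that("mixing is the exact linear model at zero noise", {
  p <- generateProfiles(100, profileConfig(nDegPerGroup = 0,
                                           nDmpPerGroup = 0), seed = 2)
  # one sample of pure macrophages
  fr <- data.frame(sample_id = "S1", group = "control",
                   AM = 100, NG = 0, EO = 0, LY = 0, MO = 0, CC = 0, SC = 0)
  mx <- mixProfiles(p, fr, noiseSd = c(expression = 0, methylation = 0))
  expect_equal(unname(omicsMatrix(mx$methylation)[, 1]),
               unname(p$methylation$control["AM", ]), tolerance = 1e-12)
  expect_equal(unname(omicsMatrix(mx$expression)[, 1]),
               unname(p$expression$control["AM", ]), tolerance = 1e-12)
  # 50/50 mixing averages the two profiles
  fr2 <- data.frame(sample_id = "S1", group = "control",
                    AM = 50, NG = 50, EO = 0, LY = 0, MO = 0, CC = 0, SC = 0)
  mx2 <- mixProfiles(p, fr2, noiseSd = c(expression = 0, methylation = 0))
  expect_equal(unname(omicsMatrix(mx2$methylation)[, 1]),
               unname((p$methylation$control["AM", ] +
                         p$methylation$control["NG", ]) / 2),
               tolerance = 1e-12)
  # conservation: observed = F B exactly for a multi-sample draw
  fr3 <- generateCellFractions("asthma", 6, seed = 3)
  mx3 <- mixProfiles(p, fr3, noiseSd = c(expression = 0, methylation = 0))
  FB <- t((as.matrix(fr3[, p$cellTypes]) / 100) %*% p$methylation$asthma)
  expect_lt(max(abs(omicsMatrix(mx3$methylation) - FB)), 1e-12)
  expect_equal(unname(mx3$clipCounts), c(0L, 0L), tolerance = 0)
})

test_that("mixing noise has the configured scale and is reproducible", {
  p <- generateProfiles(10000, profileConfig(markersPerType = 0,
                                             nDegPerGroup = 0,
                                             nDmpPerGroup = 0), seed = 4)
  fr <- generateCellFractions("control", 2, seed = 5)
  clean <- mixProfiles(p, fr, noiseSd = c(expression = 0, methylation = 0))
  noisy1 <- mixProfiles(p, fr, noiseSd = c(expression = 20,
                                           methylation = 0.01), seed = 6)
  noisy2 <- mixProfiles(p, fr, noiseSd = c(expression = 20,
                                           methylation = 0.01), seed = 6)
  expect_identical(omicsMatrix(noisy1$expression),
                   omicsMatrix(noisy2$expression))
  resid <- omicsMatrix(noisy1$expression) - omicsMatrix(clean$expression)
  keep <- omicsMatrix(noisy1$expression) > p$dynRange[1L] &
    omicsMatrix(noisy1$expression) < p$dynRange[2L]
  expect_lt(abs(sd(resid[keep]) - 20) / 20, 0.05)
})

test_that("degradation is multiplicative in 2^(-lambda (rinRef - RIN))", {
  m <- matrix(2^runif(50, 6, 12), 10, 5,
              dimnames = list(sprintf("p%02d", 1:10), sprintf("S%d", 1:5)))
  m[1, ] <- 2^10  # constant underlying signal for the closed-form check
  moe <- MixedOmicsExperiment(m, "expression-linear", dynRange = c(1, 2^16))
  model <- degradationModel(rinRef = 9)
  # all samples at the reference RIN: unchanged
  d0 <- injectDegradation(moe, rep(9, 5), model, seed = 1)
  expect_equal(omicsMatrix(d0), m, tolerance = 1e-12)
  # lambda = 0 everywhere: unchanged
  d1 <- injectDegradation(moe, c(4, 5, 6, 7, 8), model,
                          lambda = rep(0, 10))
  expect_equal(omicsMatrix(d1), m, tolerance = 1e-12)
  # single probe, lambda = 1: log2 value is linear in RIN, r = +1
  rin <- c(4, 5.5, 7, 8, 9)
  d2 <- injectDegradation(moe, rin, model,
                          lambda = c(1, rep(0, 9)))
  expect_equal(cor(log2(omicsMatrix(d2)[1, ]), rin), 1, tolerance = 1e-12)
  expect_error(injectDegradation(moe, rin, model, lambda = rep(-1, 10)),
               "negative")
})

test_that("dataset write/read round-trips exactly and refuses to clobber", {
  study <- cachedStudy()
  dir <- file.path(tempdir(), "sds-roundtrip")
  unlink(dir, recursive = TRUE)
  writeDataset(study, dir)
  expect_error(writeDataset(study, dir), "overwrite")
  expr <- readMatrixTSV(file.path(dir, "expression.tsv"))
  expect_identical(expr, omicsMatrix(study$expression))
  meth <- readMatrixTSV(file.path(dir, "methylation.tsv"))
  expect_identical(meth, omicsMatrix(study$methylation))
  eff <- read.delim(file.path(dir, "truth_effects.tsv"))
  expect_equal(nrow(eff), nrow(study$profiles$effects))
  unlink(dir, recursive = TRUE)
})

test_that("the study is a deterministic function of config and seed", {
  a <- simulateSputumStudy(smallStudyConfig(), seed = 77)
  b <- simulateSputumStudy(smallStudyConfig(), seed = 77)
  expect_identical(omicsMatrix(a$expression), omicsMatrix(b$expression))
  expect_identical(omicsMatrix(a$methylation), omicsMatrix(b$methylation))
  expect_identical(a$samples, b$samples)
  expect_identical(a$profiles$effects, b$profiles$effects)
  expect_identical(a$geneSets, b$geneSets)
})
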