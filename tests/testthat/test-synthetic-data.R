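test_that("generation is deterministic given the spec and replicate", {
  spec <- syntheticStudySpec(nSnps = 10, seed = 5)
  a <- generateTwoSample(spec, replicate = 2)
  b <- generateTwoSample(spec, replicate = 2)
  expect_identical(summaryData(a$exposure), summaryData(b$exposure))
  expect_identical(summaryData(a$outcome), summaryData(b$outcome))
  # byte-identical on disk too
  fa <- tempfile(); fb <- tempfile()
  writeSummaryStats(a$exposure, fa)
  writeSummaryStats(b$exposure, fb)
  expect_identical(readLines(fa), readLines(fb))
  # different replicate varies noise but not the latent truth
  c2 <- generateTwoSample(spec, replicate = 3)
  expect_identical(c2$truth$gamma, a$truth$gamma)
  expect_false(identical(summaryData(c2$exposure)$beta,
                         summaryData(a$exposure)$beta))
})

test_that("generated tables round-trip through the summary reader", {
  spec <- syntheticStudySpec(nSnps = 6, seed = 8)
  sim <- generateTwoSample(spec)
  tf <- tempfile(fileext = ".tsv")
  writeSummaryStats(sim$outcome, tf)
  back <- readSummaryStats(tf, "binary", trait = "synthetic_outcome")
  expect_equal(summaryData(back), summaryData(sim$outcome),
               tolerance = 1e-12)
})

test_that("Wald ratios approach theta as sampling noise vanishes", {
  spec <- syntheticStudySpec(nSnps = 8, theta = -0.2, nExposure = 1e12,
                             nCases = 1e12, nControls = 1e12, seed = 4)
  sim <- simulateInstrumentSet(spec)
  expect_equal(instruments(sim$set)$wald_ratio, rep(-0.2, 8),
               tolerance = 1e-3)
})

test_that("empirical sampling SEs match the analytic SEs", {
  spec <- syntheticStudySpec(nSnps = 10, seed = 55)
  lat <- generateTwoSample(spec)$truth
  bxs <- vapply(1:1000, function(r)
    summaryData(generateTwoSample(spec, replicate = r)$exposure)$beta,
    numeric(10))
  empirical <- apply(bxs, 1, sd)
  expect_equal(empirical, lat$se_exposure, tolerance = 0.1)
  expect_lt(abs(mean(empirical / lat$se_exposure) - 1), 0.03)
})

test_that("the default study scale explains about 1.3% of exposure variance", {
  spec <- syntheticStudySpec()
  truth <- generateTwoSample(spec)$truth
  expect_gt(truth$r2_true, 0.009)
  expect_lt(truth$r2_true, 0.017)
})

test_that("directional pleiotropy biases IVW as predicted; Egger resists", {
  # nExposure is raised well above the default so exposure betas are
  # nearly noise-free: the Egger slope is only consistent when the
  # instrument-exposure associations are measured without error
  spec <- syntheticStudySpec(nSnps = 41, theta = -0.15,
                             pleiotropy = "directional", nInvalid = 41,
                             muAlpha = 0.01, tau = 0.002, seed = 12,
                             nExposure = 2e6)
  truth <- generateTwoSample(spec)$truth
  reps <- 300
  est <- vapply(1:reps, function(r) {
    s <- simulateInstrumentSet(spec, replicate = r)$set
    c(ivw = mrBeta(mrIVW(s)), egger = mrBeta(mrEgger(s)),
      ic = extras(mrEgger(s))$egger_intercept)
  }, c(ivw = 0, egger = 0, ic = 0))
  # analytic bias of IVW under InSIDE: approx mean(alpha)/mean(gamma)
  # (weighted); the planted mean over the weighted mean exposure effect
  w <- 1 / truth$se_outcome^2
  biasPred <- sum(w * truth$gamma * truth$alpha) /
    sum(w * truth$gamma^2)
  biasIVW <- mean(est["ivw", ]) - spec@theta
  expect_equal(biasIVW, biasPred, tolerance = 0.25)
  expect_gt(biasIVW, 0.1)                    # material bias
  # Egger slope and intercept match their analytic conditional
  # expectations given the (fixed) latent draw: the weighted regression
  # of theta*gamma + alpha on gamma. Marginally over latent draws the
  # slope is unbiased for theta; conditionally it carries the sample
  # alpha-gamma association term, which the oracle includes.
  eggerOracle <- coef(lm(I(spec@theta * truth$gamma + truth$alpha) ~
                           truth$gamma, weights = w))
  seEgger <- sd(est["egger", ]) / sqrt(reps)
  expect_lt(abs(mean(est["egger", ]) - eggerOracle[2]),
            5 * seEgger + 0.005)
  expect_lt(abs(unname(eggerOracle[2]) - spec@theta), 0.1)
  # intercept recovers the planted mean pleiotropic effect
  seIc <- sd(est["ic", ]) / sqrt(reps)
  expect_lt(abs(mean(est["ic", ]) - eggerOracle[1]), 5 * seIc + 0.0005)
  expect_lt(abs(unname(eggerOracle[1]) - spec@muAlpha), 0.005)
})

test_that("multivariable generation honours its coefficients and determinism", {
  spec <- syntheticStudySpec(nSnps = 20, seed = 66)
  covEff <- matrix(rnorm(20, 0, 0.02), 20, 1,
                   dimnames = list(NULL, "height"))
  a <- generateMVTable(spec, covEff, 0.3, 2.5e5, replicate = 1)
  b <- generateMVTable(spec, covEff, 0.3, 2.5e5, replicate = 1)
  expect_identical(a$table@data, b$table@data)
  # all-zero covariate coefficients: primary recovery as univariable
  covEff0 <- matrix(rnorm(20, 0, 0.02), 20, 1,
                    dimnames = list(NULL, "height"))
  est <- vapply(1:80, function(r) {
    sim <- generateMVTable(spec, covEff0, 0, 2.5e5, replicate = r)
    mrBeta(mvmrIVW(sim$table)$exposure)
  }, numeric(1))
  expect_lt(abs(mean(est) - spec@theta), 4 * sd(est) / sqrt(80))
})

test_that("summary-level IVW agrees with two-stage least squares in expectation", {
  spec <- syntheticStudySpec(nSnps = 5, theta = 0.3,
                             exposureBetaRange = c(0.1, 0.25),
                             mafRange = c(0.2, 0.5), seed = 14)
  reps <- 120
  nInd <- 1500
  est <- vapply(1:reps, function(r) {
    il <- generateIndividualLevel(spec, nInd, "quantitative",
                                  replicate = r)
    G <- il$genotypes
    # per-SNP summary statistics computed from the individual data
    stats5 <- vapply(1:5, function(j) {
      fx <- lm(il$exposure ~ G[, j])
      fy <- lm(il$outcome ~ G[, j])
      c(coef(fx)[2], summary(fx)$coefficients[2, 2],
        coef(fy)[2], summary(fy)$coefficients[2, 2])
    }, numeric(4))
    s <- makeTestSet(bx = abs(stats5[1, ]),
                     by = stats5[3, ] * sign(stats5[1, ]),
                     seX = stats5[2, ], seY = stats5[4, ])
    # two-stage least squares on the same individuals
    xhat <- fitted(lm(il$exposure ~ G))
    c(ivw = mrBeta(mrIVW(s)), tsls = unname(coef(lm(il$outcome ~ xhat))[2]))
  }, c(ivw = 0, tsls = 0))
  d <- est["ivw", ] - est["tsls", ]
  expect_lt(abs(mean(d)), 4 * sd(d) / sqrt(reps) + 0.01)
  expect_gt(cor(est["ivw", ], est["tsls", ]), 0.95)
})
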