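test_that("IVW reduces to the Wald ratio and the homogeneous limit", {
  single <- makeTestSet(0.1, 0.05, 0.01, 0.01)
  e <- mrIVW(single)
  expect_equal(mrBeta(e), 0.5)
  expect_equal(mrSE(e), 0.1)
  expect_equal(extras(e)$re_scale_factor, 1)

  # identical Wald ratios: estimate is the common ratio, Q = 0, scale 1
  bx <- c(0.02, 0.03, 0.04)
  homo <- makeTestSet(bx, 0.4 * bx, 0.003, c(0.008, 0.010, 0.006))
  e2 <- mrIVW(homo)
  expect_equal(mrBeta(e2), 0.4)
  expect_equal(extras(e2)$q, 0)
  expect_equal(extras(e2)$re_scale_factor, 1)
})

test_that("IVW equals the weighted-least-squares oracle on the 5-SNP fixture", {
  set <- fixtureSet5()
  d <- instruments(set)
  oracle <- lm(beta_outcome ~ beta_exposure - 1, data = d,
               weights = 1 / d$se_outcome^2)
  e <- mrIVW(set, randomEffects = FALSE)
  expect_equal(mrBeta(e), unname(coef(oracle)), tolerance = 1e-12)
  # fixed-effects SE from the analytic closed form
  w <- 1 / d$se_outcome^2
  expect_equal(mrSE(e), sqrt(1 / sum(w * d$beta_exposure^2)),
               tolerance = 1e-12)
  # random-effects scale floored at 1, never below fixed effects
  eRE <- mrIVW(set, randomEffects = TRUE)
  expect_gte(mrSE(eRE), mrSE(e))
  expect_equal(mrSE(eRE) / mrSE(e), extras(eRE)$re_scale_factor)
})

test_that("MR-Egger recovers exact linear data and matches the lm oracle", {
  bx <- c(0.018, 0.024, 0.030, 0.036, 0.042)
  seY <- c(0.006, 0.009, 0.005, 0.011, 0.007)
  exact <- makeTestSet(bx, 0.003 + 0.5 * bx, 0.003, seY)
  e <- mrEgger(exact)
  expect_equal(mrBeta(e), 0.5, tolerance = 1e-10)
  expect_equal(extras(e)$egger_intercept, 0.003, tolerance = 1e-10)
  expect_equal(extras(e)$re_scale_factor, 1)  # floored at 1 on exact fit

  set <- fixtureSet5()
  d <- instruments(set)
  oracle <- lm(beta_outcome ~ beta_exposure, data = d,
               weights = 1 / d$se_outcome^2)
  eF <- mrEgger(set, randomEffects = FALSE)
  expect_equal(mrBeta(eF), unname(coef(oracle)[2]), tolerance = 1e-12)
  expect_equal(extras(eF)$egger_intercept, unname(coef(oracle)[1]),
               tolerance = 1e-12)
  # intercept p uses t on L - 2 df
  ic <- extras(mrEgger(set))
  tstat <- ic$egger_intercept / ic$egger_intercept_se
  expect_equal(ic$egger_intercept_p, 2 * pt(-abs(tstat), df = 3))
  expect_error(mrEgger(makeTestSet(c(0.1, 0.2), c(0.05, 0.1), 0.01, 0.01)),
               "egger_underdetermined")
})

test_that("Egger intercept false-positive rate is near nominal under balanced pleiotropy", {
  spec <- syntheticStudySpec(nSnps = 41, pleiotropy = "balanced",
                             nInvalid = 41, tau = 0.015, seed = 97)
  reject <- vapply(1:500, function(r) {
    s <- simulateInstrumentSet(spec, replicate = r)$set
    extras(mrEgger(s))$egger_intercept_p < 0.05
  }, logical(1))
  # binomial 3.5 sigma band around 5% at 500 replicates
  expect_gt(mean(reject), 0.05 - 0.035)
  expect_lt(mean(reject), 0.05 + 0.035)
})

test_that("weighted median interpolates the cumulative weight midpoints", {
  # equal weights, odd count: the middle ratio
  bx <- c(0.1, 0.1, 0.1)
  eq <- makeTestSet(bx, c(0.01, 0.05, 0.09), 0.003, 0.01)
  expect_equal(mrBeta(mrWeightedMedian(eq, nBoot = 0)), 0.5)

  # degenerate: all ratios equal regardless of weights
  deg <- makeTestSet(c(0.1, 0.2, 0.4), c(0.05, 0.10, 0.20), 0.003,
                     c(0.004, 0.02, 0.01))
  expect_equal(mrBeta(mrWeightedMedian(deg, nBoot = 0)), 0.5)

  # unequal weights: brute-force interpolation oracle
  set <- fixtureSet5()
  d <- instruments(set)
  r <- d$wald_ratio
  w <- 1 / d$wald_se^2
  ord <- order(r)
  r <- r[ord]; w <- w[ord] / sum(w)
  cum <- numeric(5)
  run <- 0
  for (j in 1:5) {                       # hand-enumerated midpoints
    run <- run + w[j]
    cum[j] <- run - w[j] / 2
  }
  below <- max(which(cum < 0.5))
  oracle <- r[below] + (r[below + 1] - r[below]) *
    (0.5 - cum[below]) / (cum[below + 1] - cum[below])
  expect_equal(mrBeta(mrWeightedMedian(set, nBoot = 0)), oracle,
               tolerance = 1e-12)
})

test_that("weighted median bootstrap SE is reproducible under a seed", {
  set <- fixtureSet5()
  e1 <- mrWeightedMedian(set, nBoot = 300, seed = 5)
  e2 <- mrWeightedMedian(set, nBoot = 300, seed = 5)
  expect_identical(mrSE(e1), mrSE(e2))
  expect_true(is.finite(mrSE(e1)) && mrSE(e1) > 0)
})

test_that("weighted mode tracks the majority cluster and its density oracle", {
  # 7 ratios near 0.4, 2 outliers at 2.0: estimate sides with the cluster
  bx <- rep(0.1, 9)
  by <- c(0.0395, 0.0398, 0.0400, 0.0401, 0.0402, 0.0404, 0.0399,
          0.2000, 0.2001)
  clus <- makeTestSet(bx, by, 0.003, 0.01)
  est <- mrBeta(mrWeightedMode(clus, nBoot = 0))
  expect_lt(abs(est - 0.4), abs(est - 2.0))

  # degenerate: all ratios identical
  deg <- makeTestSet(c(0.1, 0.2, 0.4), c(0.05, 0.10, 0.20), 0.003, 0.01)
  expect_equal(mrBeta(mrWeightedMode(deg, nBoot = 0)), 0.5)

  # grid argmax equals an explicitly summed kernel-density oracle
  set <- fixtureSet5()
  d <- instruments(set)
  r <- d$wald_ratio
  w <- (1 / d$wald_se^2); w <- w / sum(w)
  h <- 1 * 0.9 * min(sd(r), mad(r)) * length(r)^(-1 / 5)
  grid <- seq(min(r) - 3 * h, max(r) + 3 * h, length.out = 2048)
  dens <- numeric(length(grid))
  for (g in seq_along(grid))                 # brute-force double loop
    for (j in seq_along(r))
      dens[g] <- dens[g] + w[j] * dnorm(grid[g], r[j], h)
  expect_equal(mrBeta(mrWeightedMode(set, nBoot = 0)),
               grid[which.max(dens)], tolerance = 1e-12)
})

test_that("penalised robust IVW matches IVW without outliers and resists one", {
  # exact-fit data: no penalty binds, estimate equals weighted least squares
  bx <- c(0.018, 0.024, 0.030, 0.036, 0.042)
  exact <- makeTestSet(bx, 0.5 * bx, 0.003, c(0.006, 0.009, 0.005, 0.011,
                                              0.007))
  e <- mrPenalisedRobustIVW(exact)
  expect_equal(mrBeta(e), 0.5, tolerance = 1e-10)
  expect_equal(extras(e)$n_penalised, 0)

  # mildly noisy homogeneous data: close to plain IVW
  spec <- syntheticStudySpec(nSnps = 20, seed = 5)
  s <- simulateInstrumentSet(spec)$set
  expect_lt(abs(mrBeta(mrPenalisedRobustIVW(s)) - mrBeta(mrIVW(s))), 0.06)

  # planted outlier: penalised estimate closer to the clean-data IVW
  clean <- simulateInstrumentSet(syntheticStudySpec(nSnps = 25,
                                                    seed = 19))$set
  thetaClean <- mrBeta(mrIVW(clean))
  d <- instruments(clean)
  d$beta_outcome[1] <- d$beta_outcome[1] + 0.15   # gross direct effect
  d$wald_ratio <- d$beta_outcome / d$beta_exposure
  dirty <- makeTestSet(d$beta_exposure, d$beta_outcome, d$se_exposure,
                       d$se_outcome, snp = d$snp)
  ePen <- mrPenalisedRobustIVW(dirty)
  eIVW <- mrIVW(dirty)
  expect_gt(extras(ePen)$n_penalised, 0)
  expect_lt(abs(mrBeta(ePen) - thetaClean), abs(mrBeta(eIVW) - thetaClean))
})

test_that("estimators are invariant to instrument order", {
  set <- fixtureSet5()
  perm <- set[c(4, 1, 5, 2, 3)]
  for (fn in list(function(s) mrIVW(s),
                  function(s) mrEgger(s),
                  function(s) mrWeightedMedian(s, nBoot = 0),
                  function(s) mrWeightedMode(s, nBoot = 0),
                  function(s) mrPenalisedRobustIVW(s)))
    expect_equal(mrBeta(fn(perm)), mrBeta(fn(set)), tolerance = 1e-10)
})

test_that("estimators are invariant to joint sign flips at harmonisation", {
  # flipping (beta_exposure, beta_outcome) of some SNPs before orientation
  # yields the same instrument set, hence identical estimates
  spec <- syntheticStudySpec(nSnps = 10, seed = 23)
  sim <- generateTwoSample(spec)
  flipped <- sim$exposure
  fd <- flipped@data
  j <- c(2, 5, 7)
  fd$beta[j] <- -fd$beta[j]
  fd$eaf[j] <- 1 - fd$eaf[j]
  ea <- fd$effect_allele[j]
  fd$effect_allele[j] <- fd$other_allele[j]
  fd$other_allele[j] <- ea
  flipped@data <- fd
  odFlip <- sim$outcome
  od <- odFlip@data
  od$beta[j] <- -od$beta[j]
  od$eaf[j] <- 1 - od$eaf[j]
  od$effect_allele[j] <- fd$effect_allele[j]
  od$other_allele[j] <- fd$other_allele[j]
  odFlip@data <- od
  s1 <- harmoniseInstruments(sim$exposure, sim$outcome)
  s2 <- harmoniseInstruments(flipped, odFlip)
  expect_equal(instruments(s2)$wald_ratio, instruments(s1)$wald_ratio)
  expect_equal(mrBeta(mrIVW(s2)), mrBeta(mrIVW(s1)))
  expect_equal(mrBeta(mrEgger(s2)), mrBeta(mrEgger(s1)))
})
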