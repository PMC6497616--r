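#' Specify a synthetic two-sample MR study
#'
#' Builds a \linkS4class{SyntheticStudySpec}. The defaults emulate the
#' scale of a 41-SNP instrument for a standardised quantitative exposure
#' measured in a GWAS of ~144k individuals against a case-control outcome
#' meta-analysis of ~123k cases and ~106k controls, with per-SNP effects
#' whose total variance explained is about 1.3\%; all parameters are
#' overridable.
#'
#' @param nSnps number of independent instrument SNPs.
#' @param theta true causal effect, log-odds per 1-SD exposure.
#' @param mafRange range for uniform minor-allele-frequency draws,
#'   within (0, 0.5].
#' @param exposureBetaRange range for uniform per-allele exposure effects
#'   (SD units).
#' @param nExposure exposure-GWAS sample size.
#' @param nCases,nControls outcome-GWAS case/control counts.
#' @param pleiotropy \code{"none"}, \code{"balanced"} (mean-zero direct
#'   effects), \code{"directional"} (mean \code{muAlpha}), or
#'   \code{"inside_violating"} (directional effects correlated with
#'   instrument strength at correlation \code{rho}).
#' @param nInvalid number of SNPs given pleiotropic direct effects.
#' @param tau SD of the pleiotropic effects.
#' @param muAlpha mean pleiotropic effect (directional models).
#' @param rho pleiotropy-instrument-strength correlation
#'   (\code{"inside_violating"} only).
#' @param seed integer seed; identical specs generate identical data.
#' @return a \linkS4class{SyntheticStudySpec}.
#' @export
syntheticStudySpec <- function(nSnps = 41L, theta = -0.15,
                               mafRange = c(0.1, 0.5),
                               exposureBetaRange = c(0.015, 0.04),
                               nExposure = 143677, nCases = 122977,
                               nControls = 105974,
                               pleiotropy = "none", nInvalid = 0L,
                               tau = 0, muAlpha = 0, rho = 0,
                               seed = 1L) {
  new("SyntheticStudySpec", nSnps = as.integer(nSnps), theta = theta,
      mafRange = mafRange, exposureBetaRange = exposureBetaRange,
      nExposure = nExposure, nCases = nCases, nControls = nControls,
      pleiotropy = pleiotropy, nInvalid = as.integer(nInvalid),
      tau = tau, muAlpha = muAlpha, rho = rho, seed = as.integer(seed))
}

## Latent quantities (frequencies, true effects, pleiotropic effects,
## invalid-SNP ids) are drawn once per spec from spec@seed, so replicate
## variation isolates sampling noise. Noise streams are keyed off seed and
## replicate; the multiplier keeps derived seeds within 32-bit range.
.latentDraws <- function(spec) {
  set.seed(spec@seed)
  n <- spec@nSnps
  maf <- runif(n, spec@mafRange[1], spec@mafRange[2])
  gamma <- runif(n, spec@exposureBetaRange[1], spec@exposureBetaRange[2])
  invalid <- sort(sample.int(n, spec@nInvalid))
  alpha <- numeric(n)
  if (spec@nInvalid > 0 && spec@pleiotropy != "none") {
    m <- spec@nInvalid
    alpha[invalid] <- switch(spec@pleiotropy,
      balanced = rnorm(m, 0, spec@tau),
      directional = rnorm(m, spec@muAlpha, spec@tau),
      inside_violating = {
        zg <- if (m > 1 && sd(gamma[invalid]) > 0)
          as.numeric(scale(gamma[invalid])) else rep(0, m)
        spec@muAlpha + spec@tau *
          (spec@rho * zg + sqrt(1 - spec@rho^2) * rnorm(m))
      })
  }
  list(maf = maf, gamma = gamma, alpha = alpha, invalid = invalid,
       snp = sprintf("rs%06d", seq_len(n)))
}

.noiseSeed <- function(seed, replicate)
  (seed + 48271 * (replicate - 1)) %% 2147483563 + 1

#' Generate two-sample GWAS summary statistics with known truth
#'
#' Per SNP j with frequency f_j and true exposure effect gamma_j: the
#' exposure-side SE is 1/sqrt(2 f (1 - f) n_exposure) and the observed
#' exposure beta is normal about gamma_j; the outcome-side SE is
#' sqrt(N / (2 f (1 - f) n_cases n_controls)) (the case-control log-odds
#' approximation; no individual genotypes are simulated) and the observed
#' outcome beta is normal about theta gamma_j + alpha_j, where alpha_j is
#' the SNP's pleiotropic direct effect (zero for valid SNPs). Latent values
#' are fixed per spec; \code{replicate} varies only the sampling noise.
#'
#' @param spec a \linkS4class{SyntheticStudySpec}.
#' @param replicate replicate index (>= 1) for the noise stream.
#' @return list with \code{exposure} and \code{outcome}
#'   (\linkS4class{SummaryStats}) and \code{truth} (theta, per-SNP maf,
#'   gamma, alpha, invalid SNP ids, analytic SEs, true variance explained).
#' @export
generateTwoSample <- function(spec, replicate = 1L) {
  stopifnot(is(spec, "SyntheticStudySpec"), replicate >= 1)
  lat <- .latentDraws(spec)
  n <- spec@nSnps
  vg <- 2 * lat$maf * (1 - lat$maf)
  seX <- 1 / sqrt(vg * spec@nExposure)
  nTot <- spec@nCases + spec@nControls
  seY <- sqrt(nTot / (vg * spec@nCases * spec@nControls))
  set.seed(.noiseSeed(spec@seed, replicate))
  bx <- rnorm(n, lat$gamma, seX)
  by <- rnorm(n, spec@theta * lat$gamma + lat$alpha, seY)
  mkTab <- function(beta, se, nSamp, kind, trait) {
    d <- data.frame(snp = lat$snp, effect_allele = "A", other_allele = "G",
                    eaf = lat$maf, beta = beta, se = se,
                    pvalue = pmax(2 * pnorm(-abs(beta / se)), 1e-300),
                    n = nSamp,
                    stringsAsFactors = FALSE)
    new("SummaryStats", data = d, trait = trait, traitKind = kind)
  }
  list(exposure = mkTab(bx, seX, spec@nExposure, "quantitative",
                        "synthetic_exposure"),
       outcome = mkTab(by, seY, nTot, "binary", "synthetic_outcome"),
       truth = list(theta = spec@theta, maf = lat$maf, gamma = lat$gamma,
                    alpha = lat$alpha, invalid = lat$snp[lat$invalid],
                    se_exposure = seX, se_outcome = seY,
                    r2_true = sum(vg * lat$gamma^2)))
}

#' Generate a harmonised synthetic instrument set in one call
#'
#' Convenience wrapper: \code{\link{generateTwoSample}} followed by
#' \code{\link{harmoniseInstruments}}.
#'
#' @param spec a \linkS4class{SyntheticStudySpec}.
#' @param replicate noise-stream replicate index.
#' @param name set label.
#' @return list with \code{set} (an \linkS4class{InstrumentSet}) and
#'   \code{truth}.
#' @export
simulateInstrumentSet <- function(spec, replicate = 1L,
                                  name = "synthetic") {
  sim <- generateTwoSample(spec, replicate)
  list(set = harmoniseInstruments(sim$exposure, sim$outcome, name = name),
       truth = sim$truth)
}

#' Generate a multivariable instrument table with known truth
#'
#' Extends \code{\link{generateTwoSample}} with K - 1 covariate exposures:
#' outcome betas are generated from the multivariable linear model
#' theta * gamma_j + sum_k covCoefficients_k * covEffects_jk + alpha_j, and
#' each covariate's observed betas are normal about its true per-SNP
#' effects with the analytic SE for its own GWAS sample size.
#'
#' @param spec a \linkS4class{SyntheticStudySpec} (primary exposure).
#' @param covEffects numeric matrix, nSnps rows by K - 1 covariate columns,
#'   of true per-SNP covariate effects (column names name the covariates).
#' @param covCoefficients length K - 1 vector: each covariate's causal
#'   effect on the outcome.
#' @param covSampleSizes length K - 1 vector of covariate-GWAS sample
#'   sizes.
#' @param replicate noise-stream replicate index.
#' @param primaryName label of the primary exposure column.
#' @return list with \code{table} (an \linkS4class{MVInstrumentSet}) and
#'   \code{truth} (includes the full coefficient vector).
#' @export
generateMVTable <- function(spec, covEffects, covCoefficients,
                            covSampleSizes, replicate = 1L,
                            primaryName = "exposure") {
  stopifnot(is(spec, "SyntheticStudySpec"),
            nrow(covEffects) == spec@nSnps,
            ncol(covEffects) == length(covCoefficients),
            length(covSampleSizes) == length(covCoefficients))
  covNames <- colnames(covEffects)
  if (is.null(covNames))
    covNames <- paste0("cov", seq_along(covCoefficients))
  lat <- .latentDraws(spec)
  n <- spec@nSnps
  vg <- 2 * lat$maf * (1 - lat$maf)
  seX <- 1 / sqrt(vg * spec@nExposure)
  nTot <- spec@nCases + spec@nControls
  seY <- sqrt(nTot / (vg * spec@nCases * spec@nControls))
  muY <- spec@theta * lat$gamma +
    as.numeric(covEffects %*% covCoefficients) + lat$alpha
  set.seed(.noiseSeed(spec@seed, replicate))
  bx <- rnorm(n, lat$gamma, seX)
  by <- rnorm(n, muY, seY)
  d <- data.frame(snp = lat$snp, beta_outcome = by, se_outcome = seY,
                  stringsAsFactors = FALSE)
  d[[paste0("beta_", primaryName)]] <- bx
  d[[paste0("se_", primaryName)]] <- seX
  for (k in seq_along(covNames)) {
    seC <- 1 / sqrt(vg * covSampleSizes[k])
    d[[paste0("beta_", covNames[k])]] <- rnorm(n, covEffects[, k], seC)
    d[[paste0("se_", covNames[k])]] <- seC
  }
  table <- makeMVInstrumentSet(d, exposures = c(primaryName, covNames),
                               primary = primaryName, name = "syntheticMV")
  list(table = table,
       truth = list(theta = spec@theta, covCoefficients =
                      setNames(covCoefficients, covNames),
                    gamma = lat$gamma, alpha = lat$alpha,
                    invalid = lat$snp[lat$invalid]))
}

#' Individual-level generative mode
#'
#' Simulates genotypes (binomial, Hardy-Weinberg), a standardised
#' quantitative exposure built from the spec's true per-SNP effects, and an
#' outcome that is either quantitative (linear in the exposure) or binary
#' (logistic in the exposure). Slow relative to the summary-level
#' generator; intended for small-n cross-validation, e.g. checking that
#' summary-level IVW agrees with two-stage least squares on the same
#' individuals.
#'
#' @param spec a \linkS4class{SyntheticStudySpec} (its latent maf/gamma
#'   draws are reused; sample sizes come from \code{nIndividuals}).
#' @param nIndividuals number of individuals to simulate.
#' @param outcomeKind \code{"quantitative"} or \code{"binary"}.
#' @param replicate noise-stream replicate index.
#' @return list with \code{genotypes} (matrix), \code{exposure},
#'   \code{outcome} (vectors) and \code{truth}.
#' @export
generateIndividualLevel <- function(spec, nIndividuals = 2000,
                                    outcomeKind = c("quantitative",
                                                    "binary"),
                                    replicate = 1L) {
  outcomeKind <- match.arg(outcomeKind)
  lat <- .latentDraws(spec)
  n <- spec@nSnps
  vg <- sum(2 * lat$maf * (1 - lat$maf) * lat$gamma^2)
  if (vg >= 1) stop("per-SNP effects imply variance explained >= 1")
  set.seed(.noiseSeed(spec@seed, replicate) + 1L)
  G <- vapply(seq_len(n), function(j)
    rbinom(nIndividuals, 2L, lat$maf[j]), numeric(nIndividuals))
  colnames(G) <- lat$snp
  x <- as.numeric(G %*% lat$gamma) + rnorm(nIndividuals, 0, sqrt(1 - vg))
  y <- if (outcomeKind == "quantitative")
    spec@theta * x + rnorm(nIndividuals)
  else
    rbinom(nIndividuals, 1L, stats::plogis(spec@theta * x))
  list(genotypes = G, exposure = x, outcome = y,
       truth = list(theta = spec@theta, gamma = lat$gamma,
                    maf = lat$maf))
}

#' Write a SummaryStats object as a GWAS summary TSV
#'
#' Emits the same tab-separated dialect \code{\link{readSummaryStats}}
#' consumes (columns snp, effect_allele, other_allele, eaf, beta, se,
#' pvalue, n), so generated data round-trip through the reader.
#'
#' @param x a \linkS4class{SummaryStats}.
#' @param path output path.
#' @export
writeSummaryStats <- function(x, path) {
  stopifnot(is(x, "SummaryStats"))
  utils::write.table(x@data, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
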