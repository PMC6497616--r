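#' @import methods
#' @importFrom stats approx coef cooks.distance dnorm lm mad median pchisq pf
#'   pnorm pt qf qnorm rbinom rnorm runif sd setNames rstudent vcov
NULL

.SUMMARY_COLS <- c("snp", "effect_allele", "other_allele", "eaf",
                   "beta", "se", "pvalue", "n")

.INSTRUMENT_COLS <- c("snp", "proxy_of", "proxy_r2",
                      "effect_allele", "other_allele", "eaf",
                      "beta_exposure", "se_exposure", "pvalue_exposure",
                      "beta_outcome", "se_outcome", "pvalue_outcome",
                      "wald_ratio", "wald_se")

#' SummaryStats: per-SNP association statistics for one trait
#'
#' A table of single-SNP association results from one GWAS: per SNP the
#' effect and other allele, effect-allele frequency (possibly missing),
#' per-allele beta (SD units for a quantitative trait, log-odds for a binary
#' trait), its standard error, p-value and sample size.
#'
#' @slot data data.frame with columns \code{snp}, \code{effect_allele},
#'   \code{other_allele}, \code{eaf}, \code{beta}, \code{se}, \code{pvalue},
#'   \code{n}.
#' @slot trait character(1), trait label.
#' @slot traitKind \code{"quantitative"} or \code{"binary"}.
#'
#' @exportClass SummaryStats
setClass("SummaryStats",
         slots = c(data = "data.frame",
                   trait = "character",
                   traitKind = "character"))

setValidity("SummaryStats", function(object) {
  d <- object@data
  msgs <- character()
  missing_cols <- setdiff(.SUMMARY_COLS, names(d))
  if (length(missing_cols))
    return(paste("missing columns:", paste(missing_cols, collapse = ", ")))
  if (!object@traitKind %in% c("quantitative", "binary"))
    msgs <- c(msgs, "traitKind must be 'quantitative' or 'binary'")
  if (nrow(d)) {
    if (any(!is.na(d$se) & d$se <= 0))
      msgs <- c(msgs, "se must be > 0")
    if (any(!is.na(d$eaf) & (d$eaf < 0 | d$eaf > 1)))
      msgs <- c(msgs, "eaf must lie in [0, 1]")
    if (any(!is.na(d$pvalue) & (d$pvalue <= 0 | d$pvalue > 1)))
      msgs <- c(msgs, "pvalue must lie in (0, 1]")
    if (anyDuplicated(d$snp))
      msgs <- c(msgs, "duplicated snp identifiers")
  }
  if (length(msgs)) msgs else TRUE
})

#' InstrumentSet: harmonised exposure/outcome instruments
#'
#' A named collection of SNP instruments after allele alignment: paired
#' exposure and outcome effects (plus optional covariate-trait effects),
#' per-SNP Wald ratios, and the provenance of every filtering decision.
#' All rows are oriented to the exposure-increasing allele, so
#' \code{beta_exposure > 0} throughout.
#'
#' @slot name character(1), e.g. \code{"IV41"}.
#' @slot data data.frame, one row per SNP (see \code{instruments()}).
#' @slot covariates named list of data.frames (\code{snp}, \code{beta},
#'   \code{se}, \code{pvalue}), one per covariate trait, aligned to the same
#'   allele orientation. \code{beta}/\code{se} are \code{NA} for traits
#'   supplying only p-values.
#' @slot filterLog data.frame (\code{snp}, \code{trait}, \code{pvalue},
#'   \code{threshold}, \code{action}) recording pleiotropy-filter decisions.
#' @slot exclusions data.frame (\code{snp}, \code{reason}) of SNPs dropped
#'   during harmonisation.
#'
#' @exportClass InstrumentSet
setClass("InstrumentSet",
         slots = c(name = "character",
                   data = "data.frame",
                   covariates = "list",
                   filterLog = "data.frame",
                   exclusions = "data.frame"))

setValidity("InstrumentSet", function(object) {
  d <- object@data
  msgs <- character()
  missing_cols <- setdiff(.INSTRUMENT_COLS, names(d))
  if (length(missing_cols))
    return(paste("missing columns:", paste(missing_cols, collapse = ", ")))
  if (nrow(d)) {
    if (any(d$beta_exposure <= 0))
      msgs <- c(msgs, "beta_exposure must be > 0 after orientation")
    if (any(!is.finite(d$wald_ratio)))
      msgs <- c(msgs, "wald_ratio must be finite")
    if (any(abs(d$wald_se - d$se_outcome / abs(d$beta_exposure)) >
            1e-8 * d$wald_se))
      msgs <- c(msgs, "wald_se must equal se_outcome/|beta_exposure|")
    if (any(!is.na(d$proxy_r2) & (d$proxy_r2 <= 0 | d$proxy_r2 > 1)))
      msgs <- c(msgs, "proxy_r2 must lie in (0, 1]")
  }
  if (length(object@covariates) &&
      is.null(names(object@covariates)))
    msgs <- c(msgs, "covariates list must be named by trait")
  if (length(msgs)) msgs else TRUE
})

#' MREstimate: one causal-effect estimate
#'
#' The result of one MR estimator: causal effect on the log-odds (or outcome)
#' scale per 1-SD exposure, its standard error, 95\% confidence interval and
#' two-sided p-value, with method-specific extras (Egger intercept terms,
#' random-effects scale factor, instrument count).
#'
#' @slot method character(1).
#' @slot beta,se,ciLower,ciUpper,pvalue numeric(1).
#' @slot nSNPs integer(1), instruments used.
#' @slot extras named list.
#'
#' @exportClass MREstimate
setClass("MREstimate",
         slots = c(method = "character",
                   beta = "numeric", se = "numeric",
                   ciLower = "numeric", ciUpper = "numeric",
                   pvalue = "numeric",
                   nSNPs = "integer",
                   extras = "list"))

setValidity("MREstimate", function(object) {
  msgs <- character()
  if (!is.na(object@ciLower) && !is.na(object@ciUpper) &&
      object@ciLower >= object@ciUpper)
    msgs <- c(msgs, "ciLower must be < ciUpper")
  if (!is.na(object@se) && object@se < 0)
    msgs <- c(msgs, "se must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' HeterogeneityReport: Cochran's Q and influence flags
#'
#' Between-instrument heterogeneity of the Wald ratios under the IVW model:
#' Cochran's Q, its degrees of freedom (L - 1) and chi-square p-value, each
#' SNP's contribution to Q, and the SNPs flagged by the influence methods.
#'
#' @slot q,pvalue numeric(1).
#' @slot df integer(1).
#' @slot perSNP named numeric, per-SNP Q contributions (sums to \code{q}).
#' @slot flagged named list of character vectors (per influence method).
#'
#' @exportClass HeterogeneityReport
setClass("HeterogeneityReport",
         slots = c(q = "numeric", df = "integer", pvalue = "numeric",
                   perSNP = "numeric", flagged = "list"))

setValidity("HeterogeneityReport", function(object) {
  msgs <- character()
  if (length(object@perSNP) &&
      abs(sum(object@perSNP) - object@q) > 1e-8 * max(1, object@q))
    msgs <- c(msgs, "perSNP contributions must sum to q")
  if (any(object@perSNP < 0))
    msgs <- c(msgs, "perSNP contributions must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' MVInstrumentSet: instruments for multivariable MR
#'
#' Per-SNP outcome betas/SEs alongside betas/SEs for K exposures
#' (typically K >= 2; K = 1 reduces to the univariable model), all rows
#' oriented to the primary exposure-increasing allele.
#'
#' @slot name character(1).
#' @slot data data.frame with \code{snp}, \code{beta_outcome},
#'   \code{se_outcome} and \code{beta_<exposure>}, \code{se_<exposure>}
#'   columns for each exposure.
#' @slot exposures character, exposure names (column suffixes).
#' @slot primary character(1), the exposure of interest.
#'
#' @exportClass MVInstrumentSet
setClass("MVInstrumentSet",
         slots = c(name = "character",
                   data = "data.frame",
                   exposures = "character",
                   primary = "character"))

setValidity("MVInstrumentSet", function(object) {
  d <- object@data
  msgs <- character()
  if (length(object@exposures) < 1)
    msgs <- c(msgs, "need at least one exposure")
  if (!object@primary %in% object@exposures)
    msgs <- c(msgs, "primary must be one of the exposures")
  need <- c("snp", "beta_outcome", "se_outcome",
            paste0("beta_", object@exposures),
            paste0("se_", object@exposures))
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols))
    msgs <- c(msgs, paste("missing columns:",
                          paste(missing_cols, collapse = ", ")))
  else {
    bmat <- as.matrix(d[, paste0("beta_", object@exposures), drop = FALSE])
    if (anyNA(bmat))
      msgs <- c(msgs, "missing exposure betas are not allowed")
    if (nrow(d) && any(d[[paste0("beta_", object@primary)]] <= 0))
      msgs <- c(msgs, "rows must be oriented to the primary exposure-increasing allele")
  }
  if (length(msgs)) msgs else TRUE
})

#' SyntheticStudySpec: generative parameters for the simulator
#'
#' Parameters of the two-sample summary-statistics generator: SNP count,
#' true causal effect (log-odds per SD exposure), minor-allele-frequency and
#' per-allele exposure-effect ranges, the exposure-GWAS sample size and the
#' case/control counts of the outcome GWAS, a pleiotropy architecture, and
#' the seed. Defaults emulate the scale of a 41-SNP birth-weight instrument
#' against a large breast-cancer case-control meta-analysis.
#'
#' @slot nSnps,nInvalid integer(1).
#' @slot theta numeric(1), true causal log-odds per 1-SD exposure.
#' @slot mafRange,exposureBetaRange numeric(2).
#' @slot nExposure,nCases,nControls numeric(1).
#' @slot pleiotropy one of \code{"none"}, \code{"balanced"},
#'   \code{"directional"}, \code{"inside_violating"}.
#' @slot tau numeric(1), SD of pleiotropic effects.
#' @slot muAlpha numeric(1), mean directional pleiotropic effect.
#' @slot rho numeric(1), correlation between pleiotropy and instrument
#'   strength (InSIDE violation).
#' @slot seed integer(1).
#'
#' @exportClass SyntheticStudySpec
setClass("SyntheticStudySpec",
         slots = c(nSnps = "integer", theta = "numeric",
                   mafRange = "numeric", exposureBetaRange = "numeric",
                   nExposure = "numeric", nCases = "numeric",
                   nControls = "numeric",
                   pleiotropy = "character", nInvalid = "integer",
                   tau = "numeric", muAlpha = "numeric", rho = "numeric",
                   seed = "integer"))

setValidity("SyntheticStudySpec", function(object) {
  msgs <- character()
  if (object@nInvalid > object@nSnps)
    msgs <- c(msgs, "nInvalid must be <= nSnps")
  if (object@tau < 0) msgs <- c(msgs, "tau must be >= 0")
  if (object@mafRange[1] <= 0 || object@mafRange[2] > 0.5 ||
      object@mafRange[1] > object@mafRange[2])
    msgs <- c(msgs, "mafRange must be an increasing pair within (0, 0.5]")
  if (!object@pleiotropy %in%
      c("none", "balanced", "directional", "inside_violating"))
    msgs <- c(msgs, "unknown pleiotropy model")
  if (any(c(object@nExposure, object@nCases, object@nControls) <= 0))
    msgs <- c(msgs, "sample sizes must be positive")
  if (abs(object@rho) > 1) msgs <- c(msgs, "rho must lie in [-1, 1]")
  if (length(msgs)) msgs else TRUE
})
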