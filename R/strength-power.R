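#' Variance explained from p-values and sample size
#'
#' Recovers each SNP's 1-df F statistic from the upper tail of
#' F(1, n - 2) at its exposure p-value and converts it to the variance
#' explained r2_j = F / (n - 2 + F); the instrument's total r2 is the sum
#' over (independent) SNPs. This is the route of choice when effect-allele
#' frequencies are unavailable. P-values of zero (underflow) are floored at
#' 1e-300 with a warning.
#'
#' @param pValues per-SNP exposure-association p-values in (0, 1).
#' @param n exposure-GWAS sample size.
#' @return total variance explained (scalar in [0, 1)).
#' @export
varianceExplainedPN <- function(pValues, n) {
  stopifnot(n > 2, all(pValues >= 0), all(pValues < 1))
  if (any(pValues == 0)) {
    warning("p-value(s) of 0 floored at 1e-300")
    pValues[pValues == 0] <- 1e-300
  }
  f <- qf(pValues, df1 = 1, df2 = n - 2, lower.tail = FALSE)
  sum(f / (n - 2 + f))
}

#' Variance explained from effect sizes and allele frequencies
#'
#' For a standardised quantitative trait, each independent SNP with
#' effect-allele frequency f and per-allele effect beta explains
#' 2 f (1 - f) beta^2 of the trait variance; the total is the sum. Used as
#' the generator-side ground truth where true frequencies are known.
#'
#' @param betas per-allele effects (SD units).
#' @param eafs effect-allele frequencies; any NA is an error for this
#'   method (fall back to \code{\link{varianceExplainedPN}}).
#' @return total variance explained.
#' @export
varianceExplainedFreq <- function(betas, eafs) {
  if (anyNA(eafs))
    stop("missing eaf; use varianceExplainedPN for frequency-free data")
  stopifnot(length(betas) == length(eafs), all(eafs > 0), all(eafs < 1))
  sum(2 * eafs * (1 - eafs) * betas^2)
}

#' Instrument-strength F-statistic
#'
#' F = (r2 / (1 - r2)) * ((n - k - 1) / k) for an instrument of k SNPs
#' explaining r2 of the exposure variance in a GWAS of n individuals.
#' F below 10 conventionally flags a weak instrument.
#'
#' @param r2 variance explained, in (0, 1).
#' @param n exposure-GWAS sample size (> k + 1).
#' @param k number of SNPs in the instrument.
#' @return numeric with attribute \code{"weak"} (TRUE when F < 10).
#' @examples
#' fStatistic(0.013, 143677, 41)  # 46.1
#' @export
fStatistic <- function(r2, n, k) {
  stopifnot(r2 >= 0, r2 < 1, n > k + 1, k >= 1)
  f <- (r2 / (1 - r2)) * ((n - k - 1) / k)
  structure(f, weak = f < 10)
}

#' A priori power for a binary outcome
#'
#' Two-sided a priori power of a two-sample MR analysis with a case-control
#' outcome: with N = cases + controls, case fraction phi and
#' b = |log orDetect| per 1-SD exposure,
#' power = Phi(b * sqrt(N * r2 * phi * (1 - phi)) - z_{1 - alpha/2}).
#' By construction the power depends on the odds ratio only through
#' |log OR|, so OR and 1/OR give identical power. At OR = 1 the formula
#' returns alpha / 2.
#'
#' @param r2 exposure variance explained by the instrument.
#' @param nCases,nControls outcome-GWAS case and control counts.
#' @param orDetect odds ratio per 1-SD exposure to detect.
#' @param alpha two-sided significance level (default 0.05).
#' @return power in [0, 1].
#' @examples
#' binaryOutcomePower(0.013, 122977, 105974, 1.06)  # ~0.35
#' @export
binaryOutcomePower <- function(r2, nCases, nControls, orDetect,
                               alpha = 0.05) {
  stopifnot(r2 > 0, r2 < 1, nCases > 0, nControls > 0, orDetect > 0,
            alpha > 0, alpha < 1)
  n <- nCases + nControls
  phi <- nCases / n
  b <- abs(log(orDetect))
  pnorm(b * sqrt(n * r2 * phi * (1 - phi)) - qnorm(1 - alpha / 2))
}

#' Power curve over a grid of odds ratios
#'
#' @param r2,nCases,nControls,alpha as in \code{\link{binaryOutcomePower}}.
#' @param orGrid odds ratios to evaluate.
#' @return data.frame with columns \code{or} and \code{power}.
#' @export
powerCurve <- function(r2, nCases, nControls,
                       orGrid = seq(1.01, 1.5, by = 0.01), alpha = 0.05) {
  data.frame(or = orGrid,
             power = vapply(orGrid, function(o)
               binaryOutcomePower(r2, nCases, nControls, o, alpha),
               numeric(1)))
}
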