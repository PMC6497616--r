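#' Bonferroni-corrected p-value threshold
#'
#' @param alpha family-wise significance level in (0, 1).
#' @param m number of tests (>= 1).
#' @return \code{alpha / m}.
#' @examples
#' bonferroniThreshold(0.05, 54)  # 9.26e-4
#' @export
bonferroniThreshold <- function(alpha, m) {
  stopifnot(alpha > 0, alpha < 1, m >= 1)
  alpha / m
}

#' Remove instruments with pleiotropic covariate associations
#'
#' Drops every SNP whose association p-value with any covariate trait falls
#' below \code{pThreshold}; each removal is logged with the offending trait
#' and p-value. SNPs with no p-value for a trait are treated as not tested
#' (they pass for that trait, with a logged note). Used to build nested
#' instrument sets: a genome-wide threshold (5e-8) and a Bonferroni
#' threshold (alpha / number of loci) give successively stricter filters.
#'
#' @param set an \linkS4class{InstrumentSet} whose covariate slot carries
#'   per-trait p-values.
#' @param pThreshold removal threshold; SNPs with any covariate p strictly
#'   below it are removed.
#' @param name label for the filtered set.
#' @return the filtered \linkS4class{InstrumentSet} with an extended
#'   \code{filterLog}.
#' @export
filterPleiotropic <- function(set, pThreshold, name = NULL) {
  stopifnot(is(set, "InstrumentSet"), pThreshold >= 0)
  snps <- set@data$snp
  removed <- logical(length(snps))
  log <- list()
  for (tr in names(set@covariates)) {
    cv <- set@covariates[[tr]]
    p <- cv$pvalue[match(snps, cv$snp)]
    notTested <- is.na(p)
    hit <- !notTested & p < pThreshold
    if (any(notTested))
      log[[length(log) + 1L]] <- data.frame(
        snp = snps[notTested], trait = tr, pvalue = NA_real_,
        threshold = pThreshold, action = "not_tested",
        stringsAsFactors = FALSE)
    if (any(hit))
      log[[length(log) + 1L]] <- data.frame(
        snp = snps[hit], trait = tr, pvalue = p[hit],
        threshold = pThreshold, action = "removed",
        stringsAsFactors = FALSE)
    removed <- removed | hit
  }
  if (all(removed))
    stop("pleiotropy filter removed every instrument; cannot build an ",
         "instrument set at threshold ", pThreshold)
  out <- set[which(!removed)]
  out@name <- if (is.null(name)) paste0("IV", sum(!removed)) else name
  out@filterLog <- rbind(set@filterLog,
                         do.call(rbind, c(log, list(
                           data.frame(snp = character(), trait = character(),
                                      pvalue = numeric(),
                                      threshold = numeric(),
                                      action = character(),
                                      stringsAsFactors = FALSE)))))
  validObject(out)
  out
}

#' Per-SNP Wald ratio and its standard error
#'
#' The single-SNP causal estimate beta_outcome / beta_exposure with the
#' first-order (delta-rule) standard error se_outcome / |beta_exposure|,
#' which ignores exposure-side uncertainty and matches inverse-variance
#' weighting by the outcome variance. A second-order option adds the
#' exposure-side term:
#' sqrt(se_out^2 / bx^2 + by^2 * se_exp^2 / bx^4).
#'
#' @param betaOutcome,betaExposure,seOutcome numeric vectors.
#' @param seExposure numeric vector, required when \code{secondOrder}.
#' @param secondOrder logical; include the exposure-side delta term.
#' @return data.frame with columns \code{estimate} and \code{se}.
#' @examples
#' waldRatio(0.05, 0.1, 0.01)  # estimate 0.5, se 0.1
#' @export
waldRatio <- function(betaOutcome, betaExposure, seOutcome,
                      seExposure = NULL, secondOrder = FALSE) {
  if (any(betaExposure == 0)) stop("null_instrument: beta_exposure is zero")
  est <- betaOutcome / betaExposure
  if (secondOrder) {
    if (is.null(seExposure))
      stop("seExposure is required for the second-order Wald SE")
    se <- sqrt(seOutcome^2 / betaExposure^2 +
               betaOutcome^2 * seExposure^2 / betaExposure^4)
  } else {
    se <- seOutcome / abs(betaExposure)
  }
  data.frame(estimate = est, se = se)
}
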