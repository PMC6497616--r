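#' Access the per-SNP table of a SummaryStats object
#'
#' @param x a \linkS4class{SummaryStats} object.
#' @return \code{summaryData}: the per-SNP data.frame; \code{traitName} and
#'   \code{traitKind}: character(1).
#' @name summaryStats
#' @aliases summaryData traitName traitKind
NULL

#' @rdname summaryStats
#' @export
setMethod("summaryData", "SummaryStats", function(x) x@data)

#' @rdname summaryStats
#' @export
setMethod("traitName", "SummaryStats", function(x) x@trait)

#' @rdname summaryStats
#' @export
setMethod("traitKind", "SummaryStats", function(x) x@traitKind)

setMethod("show", "SummaryStats", function(object) {
  cat("SummaryStats for trait '", object@trait, "' (",
      object@traitKind, ")\n", sep = "")
  cat(" ", nrow(object@data), "SNPs\n")
  if (nrow(object@data)) {
    print(utils::head(object@data, 3), row.names = FALSE)
    if (nrow(object@data) > 3) cat("  ...\n")
  }
})

#' Accessors for InstrumentSet objects
#'
#' \code{instruments} returns the per-SNP harmonised table;
#' \code{nInstruments} its row count; \code{instrumentName} the set label;
#' \code{exclusions} the (snp, reason) table of SNPs dropped during
#' harmonisation; \code{filterLog} the pleiotropy-filter provenance;
#' \code{covariateTraits} the covariate trait names; \code{covariateStats}
#' one covariate trait's aligned (snp, beta, se, pvalue) table.
#'
#' @param x an \linkS4class{InstrumentSet} (or \linkS4class{MVInstrumentSet}
#'   where stated).
#' @param trait character(1), a covariate trait name.
#' @name instruments
#' @aliases nInstruments instrumentName exclusions filterLog covariateTraits
#'   covariateStats
NULL

#' @rdname instruments
#' @export
setMethod("instruments", "InstrumentSet", function(x) x@data)

#' @rdname instruments
#' @export
setMethod("nInstruments", "InstrumentSet", function(x) nrow(x@data))

#' @rdname instruments
#' @export
setMethod("instrumentName", "InstrumentSet", function(x) x@name)

#' @rdname instruments
#' @export
setMethod("exclusions", "InstrumentSet", function(x) x@exclusions)

#' @rdname instruments
#' @export
setMethod("filterLog", "InstrumentSet", function(x) x@filterLog)

#' @rdname instruments
#' @export
setMethod("covariateTraits", "InstrumentSet", function(x) names(x@covariates))

#' @rdname instruments
#' @export
setMethod("covariateStats", "InstrumentSet", function(x, trait) {
  if (!trait %in% names(x@covariates))
    stop("no covariate trait '", trait, "' in this instrument set")
  x@covariates[[trait]]
})

#' @rdname instruments
#' @export
setMethod("instruments", "MVInstrumentSet", function(x) x@data)

#' @rdname instruments
#' @export
setMethod("nInstruments", "MVInstrumentSet", function(x) nrow(x@data))

#' @rdname instruments
#' @export
setMethod("instrumentName", "MVInstrumentSet", function(x) x@name)

#' Subset an InstrumentSet
#'
#' Subsets by SNP identifier, logical mask or integer index; covariate
#' tables are subset consistently. Exclusion and filter logs are carried
#' over unchanged (they are provenance, not row data).
#'
#' @param x an \linkS4class{InstrumentSet}.
#' @param i character SNP ids, logical mask, or integer indices.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "InstrumentSet", function(x, i, j, ..., drop = FALSE) {
  idx <- if (is.character(i)) match(i, x@data$snp) else i
  if (is.numeric(idx) && anyNA(idx))
    stop("unknown snp id(s) in subset")
  d <- x@data[idx, , drop = FALSE]
  rownames(d) <- NULL
  covs <- lapply(x@covariates, function(cv) {
    out <- cv[match(d$snp, cv$snp), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
  initialize(x, data = d, covariates = covs)
})

setMethod("show", "InstrumentSet", function(object) {
  cat("InstrumentSet '", object@name, "': ", nrow(object@data),
      " instruments\n", sep = "")
  if (length(object@covariates))
    cat("  covariate traits:",
        paste(names(object@covariates), collapse = ", "), "\n")
  np <- sum(!is.na(object@data$proxy_of))
  if (np) cat(" ", np, "proxy-substituted loci\n")
  if (nrow(object@exclusions))
    cat(" ", nrow(object@exclusions), "SNPs excluded during harmonisation\n")
  if (nrow(object@filterLog))
    cat(" ", sum(object@filterLog$action == "removed"),
        "SNPs removed by pleiotropy filtering\n")
})

#' Accessors for MREstimate objects
#'
#' \code{mrBeta}/\code{mrSE}/\code{pValue} return the causal log-odds
#' estimate per 1-SD exposure, its SE and two-sided p-value;
#' \code{oddsRatio} the exp-transformed (OR, lower, upper) triple;
#' \code{mrMethod} the method label; \code{extras} the method-specific list
#' (Egger intercept terms, random-effects scale, instrument count).
#'
#' @param x an \linkS4class{MREstimate}.
#' @name mrEstimate-accessors
#' @aliases mrBeta mrSE mrMethod pValue oddsRatio extras
NULL

#' @rdname mrEstimate-accessors
#' @export
setMethod("mrBeta", "MREstimate", function(x) x@beta)

#' @rdname mrEstimate-accessors
#' @export
setMethod("mrSE", "MREstimate", function(x) x@se)

#' @rdname mrEstimate-accessors
#' @export
setMethod("mrMethod", "MREstimate", function(x) x@method)

#' @rdname mrEstimate-accessors
#' @export
setMethod("pValue", "MREstimate", function(x) x@pvalue)

#' @rdname mrEstimate-accessors
#' @export
setMethod("oddsRatio", "MREstimate", function(x)
  c(or = exp(x@beta), lower = exp(x@ciLower), upper = exp(x@ciUpper)))

#' @rdname mrEstimate-accessors
#' @export
setMethod("extras", "MREstimate", function(x) x@extras)

#' @rdname mrEstimate-accessors
#' @export
setMethod("nInstruments", "MREstimate", function(x) x@nSNPs)

setMethod("show", "MREstimate", function(object) {
  or <- oddsRatio(object)
  cat(sprintf("%s estimate (%d SNPs)\n", object@method, object@nSNPs))
  cat(sprintf("  beta = %.4f (SE %.4f), 95%% CI [%.4f, %.4f], p = %.3g\n",
              object@beta, object@se, object@ciLower, object@ciUpper,
              object@pvalue))
  cat(sprintf("  OR per 1-SD exposure = %.3f (95%% CI %.3f-%.3f)\n",
              or["or"], or["lower"], or["upper"]))
  if (!is.null(object@extras$egger_intercept))
    cat(sprintf("  Egger intercept = %.4g (SE %.4g), p = %.3g\n",
                object@extras$egger_intercept,
                object@extras$egger_intercept_se,
                object@extras$egger_intercept_p))
})

#' Accessors for HeterogeneityReport objects
#'
#' \code{qStatistic} returns Cochran's Q; \code{pValue} its chi-square
#' p-value; \code{perSNPQ} the per-SNP contributions; \code{flaggedSNPs} the
#' SNPs flagged by one influence method (\code{"stepwise"}, \code{"cooks"},
#' \code{"loo"}, \code{"studentised"}).
#'
#' @param x a \linkS4class{HeterogeneityReport}.
#' @param method character(1) influence-method name; if missing, the full
#'   named list of flag sets is returned.
#' @name heterogeneity-accessors
#' @aliases qStatistic perSNPQ flaggedSNPs
NULL

#' @rdname heterogeneity-accessors
#' @export
setMethod("qStatistic", "HeterogeneityReport", function(x) x@q)

#' @rdname heterogeneity-accessors
#' @export
setMethod("pValue", "HeterogeneityReport", function(x) x@pvalue)

#' @rdname heterogeneity-accessors
#' @export
setMethod("perSNPQ", "HeterogeneityReport", function(x) x@perSNP)

#' @rdname heterogeneity-accessors
#' @export
setMethod("flaggedSNPs", "HeterogeneityReport", function(x, method) {
  if (missing(method)) return(x@flagged)
  if (!method %in% names(x@flagged))
    stop("no flag set '", method, "'; available: ",
         paste(names(x@flagged), collapse = ", "))
  x@flagged[[method]]
})

setMethod("show", "HeterogeneityReport", function(object) {
  cat(sprintf("Cochran's Q = %.3f on %d df, p = %.3g\n",
              object@q, object@df, object@pvalue))
  for (m in names(object@flagged))
    cat(sprintf("  %s flags: %s\n", m,
                if (length(object@flagged[[m]]))
                  paste(object@flagged[[m]], collapse = ", ") else "(none)"))
})

setMethod("show", "MVInstrumentSet", function(object) {
  cat("MVInstrumentSet '", object@name, "': ", nrow(object@data),
      " SNPs, ", length(object@exposures), " exposures (primary: ",
      object@primary, ")\n", sep = "")
})

setMethod("show", "SyntheticStudySpec", function(object) {
  cat("SyntheticStudySpec:", object@nSnps, "SNPs, theta =", object@theta,
      "\n  pleiotropy:", object@pleiotropy,
      sprintf("(%d invalid SNPs, tau = %g, muAlpha = %g)\n",
              object@nInvalid, object@tau, object@muAlpha))
  cat(sprintf("  n_exposure = %g; outcome %g cases / %g controls; seed %d\n",
              object@nExposure, object@nCases, object@nControls, object@seed))
})
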