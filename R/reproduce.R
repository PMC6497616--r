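#' Re-analyse published per-SNP instrument tables
#'
#' Entry point for re-running the univariable and multivariable analyses
#' from curated per-SNP tables, such as the supplementary tables that
#' accompany a published two-sample MR study exported to TSV (spreadsheet
#' readers are deliberately not a dependency; export each sheet as
#' tab-separated text). Expected files under \code{dir}:
#' \describe{
#'   \item{\code{univariable_<outcome>.tsv}}{columns \code{snp},
#'     \code{beta_exposure}, \code{se_exposure}, \code{pvalue_exposure},
#'     \code{beta_outcome}, \code{se_outcome}, \code{pvalue_outcome}, plus
#'     optional 0/1 flags \code{iv41} and \code{iv24} marking membership of
#'     the filtered instrument sets.}
#'   \item{\code{mvmr_<outcome>.tsv}}{columns \code{snp},
#'     \code{beta_outcome}, \code{se_outcome} and
#'     \code{beta_<trait>}/\code{se_<trait>} for each exposure trait, the
#'     primary trait first.}
#' }
#'
#' For the univariable table the function runs IVW (random effects) on the
#' full set and on each flagged subset, Cochran's Q with the influence
#' diagnostics and stepwise pruning on the \code{iv41} subset (falling back
#' to the full set when no flags are present), IVW on the pruned set, and
#' the outcome-association enrichment count at p < 0.05. For the
#' multivariable table it runs multivariable IVW and MR-Egger.
#'
#' @param dir directory containing the exported TSV tables.
#' @param outcome outcome label used in the file names (default
#'   \code{"overall"}).
#' @param nBoot,seed bootstrap settings passed to the median/mode
#'   estimators on the main subset.
#' @return list with \code{ivw_full}, \code{ivw_iv41}, \code{ivw_iv24},
#'   \code{estimates_iv41} (all five methods), \code{diagnostics},
#'   \code{pruned}, \code{ivw_pruned}, \code{enrichment} and \code{mvmr}
#'   (NULL where the corresponding input is absent).
#' @export
reproduceSupplement <- function(dir, outcome = "overall", nBoot = 5000,
                                seed = 1L) {
  uniPath <- file.path(dir, paste0("univariable_", outcome, ".tsv"))
  mvPath <- file.path(dir, paste0("mvmr_", outcome, ".tsv"))
  if (!file.exists(uniPath) && !file.exists(mvPath))
    stop("no reanalysis tables found under ", dir,
         " (expected univariable_", outcome, ".tsv and/or mvmr_",
         outcome, ".tsv)")
  out <- list(ivw_full = NULL, ivw_iv41 = NULL, ivw_iv24 = NULL,
              estimates_iv41 = NULL, diagnostics = NULL, pruned = NULL,
              ivw_pruned = NULL, enrichment = NULL, mvmr = NULL)
  if (file.exists(uniPath)) {
    d <- utils::read.delim(uniPath, sep = "\t", stringsAsFactors = FALSE)
    need <- c("snp", "beta_exposure", "se_exposure", "beta_outcome",
              "se_outcome")
    missing_cols <- setdiff(need, names(d))
    if (length(missing_cols))
      stop("univariable table lacks column(s): ",
           paste(missing_cols, collapse = ", "))
    full <- .instrumentSetFromTable(d, "IVfull")
    out$ivw_full <- mrIVW(full)
    out$enrichment <- if ("pvalue_outcome" %in% names(d))
      enrichmentCount(d$pvalue_outcome, 0.05) else NULL
    main <- full
    if ("iv41" %in% names(d)) {
      main <- .instrumentSetFromTable(d[d$iv41 == 1, , drop = FALSE],
                                      "IV41")
      out$ivw_iv41 <- mrIVW(main)
    }
    if ("iv24" %in% names(d))
      out$ivw_iv24 <- mrIVW(
        .instrumentSetFromTable(d[d$iv24 == 1, , drop = FALSE], "IV24"))
    if (nrow(main@data) >= 3) {
      out$estimates_iv41 <- mrEstimate(main, nBoot = nBoot, seed = seed)
      out$diagnostics <- influenceDiagnostics(main)
      out$pruned <- stepwiseQPrune(main)
      out$ivw_pruned <- mrIVW(out$pruned$set)
    }
  }
  if (file.exists(mvPath)) {
    d <- utils::read.delim(mvPath, sep = "\t", stringsAsFactors = FALSE)
    exposures <- sub("^beta_", "",
                     grep("^beta_", names(d), value = TRUE))
    exposures <- setdiff(exposures, "outcome")
    tab <- makeMVInstrumentSet(d, exposures = exposures,
                               primary = exposures[1], name = "IVmv")
    out$mvmr <- list(ivw = mvmrIVW(tab), egger = mvmrEgger(tab))
  }
  out
}

## Wrap a plain per-SNP data.frame (already sign-aligned) as an
## InstrumentSet, orienting to the exposure-increasing allele.
.instrumentSetFromTable <- function(d, name) {
  inst <- data.frame(
    snp = as.character(d$snp),
    proxy_of = if ("proxy_of" %in% names(d)) as.character(d$proxy_of)
      else NA_character_,
    proxy_r2 = if ("proxy_r2" %in% names(d)) d$proxy_r2 else NA_real_,
    effect_allele = if ("effect_allele" %in% names(d)) d$effect_allele
      else NA_character_,
    other_allele = if ("other_allele" %in% names(d)) d$other_allele
      else NA_character_,
    eaf = if ("eaf" %in% names(d)) d$eaf else NA_real_,
    beta_exposure = d$beta_exposure, se_exposure = d$se_exposure,
    pvalue_exposure = if ("pvalue_exposure" %in% names(d))
      d$pvalue_exposure else NA_real_,
    beta_outcome = d$beta_outcome, se_outcome = d$se_outcome,
    pvalue_outcome = if ("pvalue_outcome" %in% names(d))
      d$pvalue_outcome else NA_real_,
    stringsAsFactors = FALSE)
  orient <- orientToExposureIncreasing(inst)
  inst <- orient$data
  inst$wald_ratio <- inst$beta_outcome / inst$beta_exposure
  inst$wald_se <- inst$se_outcome / abs(inst$beta_exposure)
  new("InstrumentSet", name = name, data = inst[, .INSTRUMENT_COLS],
      covariates = list(),
      filterLog = data.frame(snp = character(), trait = character(),
                             pvalue = numeric(), threshold = numeric(),
                             action = character(), stringsAsFactors = FALSE),
      exclusions = orient$excluded)
}
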