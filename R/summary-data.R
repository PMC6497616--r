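## Column-name synonyms accepted by the summary-statistics reader. Matching
## is case-insensitive after mapping [ ./-] to "_".
.COLUMN_ALIASES <- list(
  snp           = c("snp", "snp_id", "rsid", "rs_id", "markername", "id",
                    "variant", "variant_id"),
  effect_allele = c("effect_allele", "ea", "a1", "allele1", "alt",
                    "tested_allele", "eff_allele"),
  other_allele  = c("other_allele", "oa", "a2", "allele2", "ref", "nea",
                    "non_effect_allele", "ref_allele"),
  eaf           = c("eaf", "effect_allele_frequency", "effect_allele_freq",
                    "freq", "freq1", "af", "maf"),
  beta          = c("beta", "b", "effect", "log_odds", "logor", "beta1"),
  se            = c("se", "stderr", "standard_error", "se_beta", "sebeta"),
  pvalue        = c("pvalue", "p", "pval", "p_value", "p_val"),
  n             = c("n", "samplesize", "sample_size", "n_total", "neff"),
  n_cases       = c("n_cases", "ncase", "ncases", "cases"),
  n_controls    = c("n_controls", "ncontrol", "ncontrols", "controls")
)

.normaliseColName <- function(x) gsub("[ ./-]+", "_", tolower(trimws(x)))

.resolveColumns <- function(cols) {
  norm <- .normaliseColName(cols)
  out <- vapply(names(.COLUMN_ALIASES), function(canon) {
    hit <- which(norm %in% .COLUMN_ALIASES[[canon]])
    if (length(hit)) hit[1L] else NA_integer_
  }, integer(1))
  out
}

#' Read a GWAS summary-statistics table
#'
#' Reads a tab-separated table of per-SNP association statistics. Column
#' names are resolved through an alias table (e.g. \code{rsid}/\code{snp},
#' \code{a1}/\code{effect_allele}, \code{pval}/\code{p}), so column order is
#' irrelevant. Rows with a missing beta or standard error are dropped with a
#' message giving the count. For binary traits with separate case/control
#' counts, \code{n} is their sum. A consistency check compares each reported
#' p-value against the two-sided normal p implied by beta/se and warns (does
#' not fail) when they disagree grossly.
#'
#' @param path path to a tab-separated file with a header.
#' @param traitKind \code{"quantitative"} or \code{"binary"}.
#' @param trait trait label stored on the result.
#' @return a \linkS4class{SummaryStats} object.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("snp\tea\toa\teaf\tbeta\tse\tp\tn",
#'              "rs1\tA\tG\t0.3\t0.02\t0.004\t6e-7\t100000"), tf)
#' readSummaryStats(tf, "quantitative", trait = "exposure")
#' @export
readSummaryStats <- function(path, traitKind = c("quantitative", "binary"),
                             trait = "trait") {
  traitKind <- match.arg(traitKind)
  if (!file.exists(path)) stop("cannot read summary file: ", path)
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  idx <- .resolveColumns(names(raw))
  required <- c("snp", "effect_allele", "other_allele", "beta", "se",
                "pvalue")
  missing_req <- required[is.na(idx[required])]
  if (length(missing_req))
    stop("required column(s) not found in ", path, ": ",
         paste(missing_req, collapse = ", "))
  num <- function(canon) {
    if (is.na(idx[canon])) rep(NA_real_, nrow(raw))
    else suppressWarnings(as.numeric(raw[[idx[canon]]]))
  }
  n <- num("n")
  if (all(is.na(n)) && !is.na(idx["n_cases"]) && !is.na(idx["n_controls"]))
    n <- num("n_cases") + num("n_controls")
  d <- data.frame(
    snp = as.character(raw[[idx["snp"]]]),
    effect_allele = toupper(trimws(as.character(raw[[idx["effect_allele"]]]))),
    other_allele = toupper(trimws(as.character(raw[[idx["other_allele"]]]))),
    eaf = num("eaf"), beta = num("beta"), se = num("se"),
    pvalue = num("pvalue"), n = n,
    stringsAsFactors = FALSE)
  bad <- is.na(d$beta) | is.na(d$se) | d$se <= 0
  if (any(bad)) {
    message("readSummaryStats: dropping ", sum(bad),
            " row(s) with missing beta/se in ", basename(path))
    d <- d[!bad, , drop = FALSE]
  }
  rownames(d) <- NULL
  ok <- !is.na(d$pvalue)
  if (any(ok)) {
    implied <- 2 * pnorm(-abs(d$beta[ok] / d$se[ok]))
    off <- abs(log(pmax(d$pvalue[ok], 1e-300)) -
               log(pmax(implied, 1e-300))) > log(10)
    if (any(off))
      warning(sum(off), " p-value(s) in ", basename(path),
              " disagree with beta/se by more than 10-fold (kept as read)")
  }
  new("SummaryStats", data = d, trait = trait, traitKind = traitKind)
}

#' Read a proxy-SNP map
#'
#' A tab-separated table with columns \code{lead_snp}, \code{proxy_snp},
#' \code{r2} giving, for each lead SNP, a linkage-disequilibrium proxy and
#' the squared correlation between the two in the relevant ancestry.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns \code{lead_snp}, \code{proxy_snp},
#'   \code{r2}.
#' @export
readProxyMap <- function(path) {
  pm <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("lead_snp", "proxy_snp", "r2")
  if (!all(need %in% names(pm)))
    stop("proxy map must have columns: ", paste(need, collapse = ", "))
  pm$r2 <- as.numeric(pm$r2)
  if (any(is.na(pm$r2) | pm$r2 <= 0 | pm$r2 > 1))
    stop("proxy r2 values must lie in (0, 1]")
  pm[, need]
}

## Align one summary table (as a data.frame) to reference effect/other
## alleles, matching by snp id. Returns list(data, excluded).
.alignTable <- function(ref, tab) {
  m <- match(ref$snp, tab$snp)
  found <- !is.na(m)
  out <- tab[m, , drop = FALSE]
  rownames(out) <- NULL
  status <- rep("missing", nrow(ref))
  direct <- found & out$effect_allele == ref$effect_allele &
    out$other_allele == ref$other_allele
  swapped <- found & out$effect_allele == ref$other_allele &
    out$other_allele == ref$effect_allele
  status[direct] <- "aligned"
  status[swapped] <- "aligned"
  status[found & !direct & !swapped] <- "allele_mismatch"
  if (any(swapped)) {
    out$beta[swapped] <- -out$beta[swapped]
    out$eaf[swapped] <- 1 - out$eaf[swapped]
    ea <- out$effect_allele[swapped]
    out$effect_allele[swapped] <- out$other_allele[swapped]
    out$other_allele[swapped] <- ea
  }
  list(data = out, status = status)
}

#' Align an outcome summary table to the exposure's effect alleles
#'
#' For each SNP shared between the two tables, the outcome record is
#' re-expressed on the exposure's effect allele: when the outcome's effect
#' allele equals the exposure's other allele the outcome beta sign is
#' flipped and its effect-allele frequency replaced by 1 - eaf (alleles
#' swapped accordingly); when the orientation already matches the record is
#' unchanged; when neither orientation reconciles the pair is excluded with
#' reason \code{"allele_mismatch"}. Alignment is idempotent. Matching uses
#' allele letters only (no strand flipping); palindromic A/T and C/G SNPs
#' are retained.
#'
#' @param exposure,outcome \linkS4class{SummaryStats} objects.
#' @return list with \code{exposure} and \code{outcome} (SummaryStats
#'   restricted to reconcilable shared SNPs, outcome aligned) and
#'   \code{excluded}, a data.frame (\code{snp}, \code{reason}) covering
#'   allele mismatches.
#' @export
alignAlleles <- function(exposure, outcome) {
  stopifnot(is(exposure, "SummaryStats"), is(outcome, "SummaryStats"))
  ed <- exposure@data
  shared <- ed[ed$snp %in% outcome@data$snp, , drop = FALSE]
  al <- .alignTable(shared, outcome@data)
  keep <- al$status == "aligned"
  excluded <- data.frame(snp = shared$snp[!keep],
                         reason = rep_len("allele_mismatch", sum(!keep)),
                         stringsAsFactors = FALSE)
  expKeep <- shared[keep, , drop = FALSE]
  rownames(expKeep) <- NULL
  list(exposure = initialize(exposure, data = expKeep),
       outcome = initialize(outcome, data = al$data[keep, , drop = FALSE]),
       excluded = excluded)
}

#' Orient harmonised instruments to the exposure-increasing allele
#'
#' Rows with a negative exposure beta have the signs of the exposure beta,
#' the outcome beta and all covariate betas flipped jointly (and allele
#' labels swapped, frequencies complemented), so that every instrument's
#' effect allele is the exposure-increasing one. The Wald ratio is unchanged
#' by construction. Rows with exposure beta exactly zero are excluded with
#' reason \code{"null_instrument"}.
#'
#' @param data data.frame of harmonised instrument rows (columns as in
#'   \code{instruments()}).
#' @param covariates optional named list of per-trait data.frames
#'   (\code{snp}, \code{beta}, \code{se}, \code{pvalue}) to flip jointly.
#' @return list(\code{data}, \code{covariates}, \code{excluded}).
#' @export
orientToExposureIncreasing <- function(data, covariates = list()) {
  zero <- data$beta_exposure == 0
  excluded <- data.frame(snp = data$snp[zero],
                         reason = rep_len("null_instrument", sum(zero)),
                         stringsAsFactors = FALSE)
  data <- data[!zero, , drop = FALSE]
  flip <- data$beta_exposure < 0
  if (any(flip)) {
    data$beta_exposure[flip] <- -data$beta_exposure[flip]
    data$beta_outcome[flip] <- -data$beta_outcome[flip]
    data$eaf[flip] <- 1 - data$eaf[flip]
    ea <- data$effect_allele[flip]
    data$effect_allele[flip] <- data$other_allele[flip]
    data$other_allele[flip] <- ea
    flipIds <- data$snp[flip]
    covariates <- lapply(covariates, function(cv) {
      j <- cv$snp %in% flipIds
      cv$beta[j] <- -cv$beta[j]
      cv
    })
  }
  rownames(data) <- NULL
  list(data = data, covariates = covariates, excluded = excluded)
}

#' Substitute linkage-disequilibrium proxies for absent lead SNPs
#'
#' For each lead SNP absent from a dataset, uses the mapped proxy when its
#' r-squared with the lead exceeds \code{minR2} and the proxy itself is
#' present in the dataset; leads without a qualifying present proxy are
#' reported as unmatched (an outcome, not an error).
#'
#' @param leadIds character vector of lead SNP identifiers.
#' @param dataset a \linkS4class{SummaryStats} object to look leads up in.
#' @param proxyMap data.frame from \code{readProxyMap}, or NULL for no
#'   substitution.
#' @param minR2 minimum r-squared for a proxy to qualify (0.6 for the
#'   univariable instrument sets, 0.8 for strongly-correlated multivariable
#'   use).
#' @return data.frame with one row per lead: \code{lead}, \code{used} (the
#'   identifier looked up in the dataset, NA if unmatched), \code{proxy_of}
#'   (NA unless a proxy was used), \code{proxy_r2}.
#' @export
substituteProxies <- function(leadIds, dataset, proxyMap = NULL,
                              minR2 = 0.6) {
  stopifnot(minR2 > 0, minR2 <= 1)
  present <- leadIds %in% dataset@data$snp
  out <- data.frame(lead = leadIds, used = ifelse(present, leadIds, NA),
                    proxy_of = NA_character_, proxy_r2 = NA_real_,
                    stringsAsFactors = FALSE)
  if (!is.null(proxyMap)) {
    for (i in which(!present)) {
      hit <- proxyMap[proxyMap$lead_snp == leadIds[i] &
                      proxyMap$r2 > minR2, , drop = FALSE]
      hit <- hit[hit$proxy_snp %in% dataset@data$snp, , drop = FALSE]
      if (nrow(hit)) {
        hit <- hit[which.max(hit$r2), ]
        out$used[i] <- hit$proxy_snp
        out$proxy_of[i] <- leadIds[i]
        out$proxy_r2[i] <- hit$r2
      }
    }
  }
  out
}

.exclusionRows <- function(snps, reason) {
  data.frame(snp = snps, reason = rep_len(reason, length(snps)),
             stringsAsFactors = FALSE)
}

.isPalindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonise exposure and outcome summary statistics into an instrument set
#'
#' The full harmonisation pipeline: proxy substitution for lead SNPs absent
#' from the outcome (or any covariate) dataset, allele alignment of the
#' outcome and covariate records to the exposure's effect allele,
#' orientation of every row to the exposure-increasing allele, and per-SNP
#' Wald ratios with first-order standard errors
#' (\code{se_outcome / |beta_exposure|}). Every excluded SNP is recorded
#' with a reason (\code{allele_mismatch}, \code{null_instrument},
#' \code{unmatched}, \code{palindromic_ambiguous}).
#'
#' @param exposure,outcome \linkS4class{SummaryStats} objects.
#' @param covariates named list of \linkS4class{SummaryStats} for covariate
#'   traits; traits supplying only p-values are carried with NA betas.
#' @param proxyMap optional data.frame from \code{readProxyMap}.
#' @param minR2 proxy r-squared threshold (default 0.6).
#' @param strictPalindromes if TRUE, drop strand-ambiguous (A/T, C/G) SNPs
#'   whose exposure effect-allele frequency lies in [0.42, 0.58]; off by
#'   default since curated lead-SNP tables are pre-matched.
#' @param name label for the resulting set.
#' @return an \linkS4class{InstrumentSet}.
#' @export
harmoniseInstruments <- function(exposure, outcome, covariates = list(),
                                 proxyMap = NULL, minR2 = 0.6,
                                 strictPalindromes = FALSE,
                                 name = "harmonised") {
  stopifnot(is(exposure, "SummaryStats"), is(outcome, "SummaryStats"))
  ed <- exposure@data
  exclusions <- data.frame(snp = character(), reason = character(),
                           stringsAsFactors = FALSE)

  if (strictPalindromes) {
    pal <- .isPalindromic(ed$effect_allele, ed$other_allele) &
      !is.na(ed$eaf) & ed$eaf >= 0.42 & ed$eaf <= 0.58
    exclusions <- rbind(exclusions,
                        .exclusionRows(ed$snp[pal],
                                       "palindromic_ambiguous"))
    ed <- ed[!pal, , drop = FALSE]
  }

  ## Proxy resolution against the outcome and every covariate dataset: a
  ## locus is kept only if the lead (or one qualifying proxy) is present in
  ## all of them; the substituted id must be consistent per dataset.
  datasets <- c(list(outcome = outcome), covariates)
  subs <- lapply(datasets, function(ds)
    substituteProxies(ed$snp, ds, proxyMap, minR2))
  matched <- Reduce(`&`, lapply(subs, function(s) !is.na(s$used)))
  exclusions <- rbind(exclusions,
                      .exclusionRows(ed$snp[!matched], "unmatched"))
  ed <- ed[matched, , drop = FALSE]
  subs <- lapply(subs, function(s) s[matched, , drop = FALSE])

  ## Outcome records keyed back to the lead id for alignment.
  outSub <- subs$outcome
  od <- outcome@data[match(outSub$used, outcome@data$snp), , drop = FALSE]
  ## A proxy is assumed to tag the lead's exposure-increasing allele when its
  ## alleles differ from the lead's; records are aligned by allele letters,
  ## so a proxy with different alleles is aligned against its own exposure
  ## record if available, else taken as reported.
  od$snp <- outSub$lead
  alOut <- .alignTable(ed, od)
  keep <- alOut$status == "aligned" |
    (alOut$status == "allele_mismatch" & !is.na(outSub$proxy_of))
  exclusions <- rbind(exclusions,
                      .exclusionRows(ed$snp[!keep], "allele_mismatch"))
  ed <- ed[keep, , drop = FALSE]
  od <- alOut$data[keep, , drop = FALSE]
  outSub <- outSub[keep, , drop = FALSE]

  covTabs <- list()
  if (length(covariates)) {
    for (tr in names(covariates)) {
      csub <- subs[[tr]][keep, , drop = FALSE]
      cd <- covariates[[tr]]@data[
        match(csub$used, covariates[[tr]]@data$snp), , drop = FALSE]
      cd$snp <- csub$lead
      alc <- .alignTable(ed, cd)
      cdA <- alc$data
      ## p-only traits (all betas NA) pass through on p-values alone
      covTabs[[tr]] <- data.frame(snp = ed$snp, beta = cdA$beta,
                                  se = cdA$se, pvalue = cdA$pvalue,
                                  stringsAsFactors = FALSE)
    }
  }

  inst <- data.frame(
    snp = ed$snp,
    proxy_of = outSub$proxy_of, proxy_r2 = outSub$proxy_r2,
    effect_allele = ed$effect_allele, other_allele = ed$other_allele,
    eaf = ed$eaf,
    beta_exposure = ed$beta, se_exposure = ed$se,
    pvalue_exposure = ed$pvalue,
    beta_outcome = od$beta, se_outcome = od$se, pvalue_outcome = od$pvalue,
    stringsAsFactors = FALSE)

  orient <- orientToExposureIncreasing(inst, covTabs)
  exclusions <- rbind(exclusions, orient$excluded)
  inst <- orient$data
  inst$wald_ratio <- inst$beta_outcome / inst$beta_exposure
  inst$wald_se <- inst$se_outcome / abs(inst$beta_exposure)
  inst <- inst[, .INSTRUMENT_COLS]

  new("InstrumentSet", name = name, data = inst,
      covariates = orient$covariates,
      filterLog = data.frame(snp = character(), trait = character(),
                             pvalue = numeric(), threshold = numeric(),
                             action = character(), stringsAsFactors = FALSE),
      exclusions = exclusions)
}

#' Write and re-read harmonised instrument tables
#'
#' \code{exportInstruments} writes the per-SNP instrument table as TSV in a
#' fixed column order (snp, proxy_of, proxy_r2, effect_allele, other_allele,
#' eaf, beta_exposure, se_exposure, pvalue_exposure, beta_outcome,
#' se_outcome, pvalue_outcome, wald_ratio, wald_se), optionally alongside
#' the exclusion log. \code{importInstruments} reads such a file back into
#' an \linkS4class{InstrumentSet}; the round trip reproduces the table
#' field-for-field.
#'
#' @param set an \linkS4class{InstrumentSet}.
#' @param path output/input TSV path.
#' @param exclusionPath optional path for the (snp, reason) exclusion log.
#' @param name set label on import.
#' @return \code{importInstruments}: an \linkS4class{InstrumentSet}.
#' @export
exportInstruments <- function(set, path, exclusionPath = NULL) {
  stopifnot(is(set, "InstrumentSet"))
  utils::write.table(set@data[, .INSTRUMENT_COLS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(exclusionPath))
    utils::write.table(set@exclusions, exclusionPath, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname exportInstruments
#' @export
importInstruments <- function(path, name = "imported") {
  d <- utils::read.delim(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  missing_cols <- setdiff(.INSTRUMENT_COLS, names(d))
  if (length(missing_cols))
    stop("instrument table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  d$proxy_of <- as.character(d$proxy_of)
  d$proxy_r2 <- as.numeric(d$proxy_r2)
  d$eaf <- as.numeric(d$eaf)
  new("InstrumentSet", name = name, data = d[, .INSTRUMENT_COLS],
      covariates = list(),
      filterLog = data.frame(snp = character(), trait = character(),
                             pvalue = numeric(), threshold = numeric(),
                             action = character(), stringsAsFactors = FALSE),
      exclusions = data.frame(snp = character(), reason = character(),
                              stringsAsFactors = FALSE))
}
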