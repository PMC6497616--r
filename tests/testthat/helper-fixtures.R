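# Fixtures are built in code; nothing is read from disk except files the
# tests themselves write to tempdir().

# Wrap per-SNP effect vectors directly as an InstrumentSet (already
# oriented: bx > 0).
makeTestSet <- function(bx, by, seX, seY, snp = NULL, name = "test") {
  L <- length(bx)
  if (is.null(snp)) snp <- sprintf("rs%03d", seq_len(L))
  d <- data.frame(
    snp = snp, proxy_of = NA_character_, proxy_r2 = NA_real_,
    effect_allele = "A", other_allele = "G", eaf = 0.3,
    beta_exposure = bx, se_exposure = seX,
    pvalue_exposure = 2 * pnorm(-abs(bx / seX)),
    beta_outcome = by, se_outcome = seY,
    pvalue_outcome = 2 * pnorm(-abs(by / seY)),
    wald_ratio = by / bx, wald_se = seY / abs(bx),
    stringsAsFactors = FALSE)
  new("InstrumentSet", name = name, data = d, covariates = list(),
      filterLog = data.frame(snp = character(), trait = character(),
                             pvalue = numeric(), threshold = numeric(),
                             action = character(), stringsAsFactors = FALSE),
      exclusions = data.frame(snp = character(), reason = character(),
                              stringsAsFactors = FALSE))
}

# A fixed 5-SNP fixture with unequal weights, used against the
# closed-form oracles.
fixtureSet5 <- function() {
  makeTestSet(bx = c(0.030, 0.022, 0.041, 0.018, 0.035),
              by = c(0.0050, -0.0012, 0.0081, 0.0040, -0.0022),
              seX = c(0.003, 0.004, 0.003, 0.005, 0.004),
              seY = c(0.006, 0.009, 0.005, 0.011, 0.007))
}

# Attach covariate p-value tables (p-only traits are beta = NA).
withCovariates <- function(set, covList) {
  set@covariates <- covList
  set
}

covTable <- function(snp, pvalue, beta = NA_real_, se = NA_real_) {
  data.frame(snp = snp, beta = beta, se = se, pvalue = pvalue,
             stringsAsFactors = FALSE)
}

# Write a SummaryStats-dialect TSV with arbitrary header names/order.
writeSummaryTSV <- function(path, rows,
                            header = c("snp", "effect_allele",
                                       "other_allele", "eaf", "beta",
                                       "se", "p", "n")) {
  writeLines(c(paste(header, collapse = "\t"),
               vapply(rows, paste, "", collapse = "\t")), path)
  path
}
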