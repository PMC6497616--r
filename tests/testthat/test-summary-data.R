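test_that("reader parses well-formed tables, drops bad rows, resolves aliases", {
  tf <- tempfile(fileext = ".tsv")
  writeSummaryTSV(tf, list(
    c("rs1", "A", "G", "0.30", "0.020", "0.004", "6e-7", "100000"),
    c("rs2", "C", "T", "0.10", "-0.015", "0.005", "0.0027", "100000"),
    c("rs3", "G", "A", "0.45", "0.030", "0.006", "5.7e-7", "100000")))
  ss <- readSummaryStats(tf, "quantitative", trait = "bw")
  expect_s4_class(ss, "SummaryStats")
  expect_equal(nrow(summaryData(ss)), 3)
  expect_equal(summaryData(ss)$beta, c(0.020, -0.015, 0.030))
  expect_identical(traitName(ss), "bw")

  # a row with se = "NA" is dropped with a message
  tf2 <- tempfile(fileext = ".tsv")
  writeSummaryTSV(tf2, list(
    c("rs1", "A", "G", "0.30", "0.020", "0.004", "6e-7", "100000"),
    c("rs2", "C", "T", "0.10", "-0.015", "NA", "0.0027", "100000")))
  expect_message(ss2 <- readSummaryStats(tf2, "quantitative"),
                 "dropping 1 row")
  expect_equal(summaryData(ss2)$snp, "rs1")

  # shuffled/aliased columns give the same records
  tf3 <- tempfile(fileext = ".tsv")
  writeLines(c("pval\tA1\tBETA\tRSID\tSE\tA2\tFreq\tN",
               "6e-7\tA\t0.020\trs1\t0.004\tG\t0.30\t100000",
               "0.0027\tC\t-0.015\trs2\t0.005\tT\t0.10\t100000",
               "5.7e-7\tG\t0.030\trs3\t0.006\tA\t0.45\t100000"), tf3)
  ss3 <- readSummaryStats(tf3, "quantitative", trait = "bw")
  expect_equal(summaryData(ss3), summaryData(ss))

  # unknown required column is fatal and names the column
  tf4 <- tempfile(fileext = ".tsv")
  writeLines(c("snp\tea\toa\teaf\tzzz\tse\tp\tn",
               "rs1\tA\tG\t0.3\t0.02\t0.004\t6e-7\t1000"), tf4)
  expect_error(readSummaryStats(tf4, "quantitative"), "beta")
  expect_error(readSummaryStats(tempfile(), "quantitative"),
               "cannot read")
})

test_that("reader warns when p-values contradict beta/se", {
  tf <- tempfile(fileext = ".tsv")
  writeSummaryTSV(tf, list(c("rs1", "A", "G", "0.3", "0.02", "0.004",
                             "0.9", "1000")))
  expect_warning(readSummaryStats(tf, "quantitative"), "disagree")
})

test_that("allele alignment follows the swap rule and rejects mismatches", {
  mkSS <- function(snp, ea, oa, beta, eaf = 0.3, se = 0.01) {
    d <- data.frame(snp = snp, effect_allele = ea, other_allele = oa,
                    eaf = eaf, beta = beta, se = se,
                    pvalue = 2 * pnorm(-abs(beta / se)), n = 1e5,
                    stringsAsFactors = FALSE)
    new("SummaryStats", data = d, trait = "t", traitKind = "quantitative")
  }
  exposure <- mkSS(c("rs1", "rs2", "rs3"), c("A", "A", "A"),
                   c("G", "G", "G"), c(0.02, 0.02, 0.02))
  outcome <- mkSS(c("rs1", "rs2", "rs3"), c("A", "G", "C"),
                  c("G", "A", "T"), c(-0.01, -0.01, -0.01), eaf = 0.3)
  al <- alignAlleles(exposure, outcome)
  od <- summaryData(al$outcome)
  # rs1 already aligned: unchanged
  expect_equal(od$beta[od$snp == "rs1"], -0.01)
  expect_equal(od$eaf[od$snp == "rs1"], 0.3)
  # rs2 swapped orientation: beta flipped, eaf complemented
  expect_equal(od$beta[od$snp == "rs2"], 0.01)
  expect_equal(od$eaf[od$snp == "rs2"], 0.7)
  # rs3 irreconcilable: excluded with reason
  expect_false("rs3" %in% od$snp)
  expect_equal(al$excluded$reason[al$excluded$snp == "rs3"],
               "allele_mismatch")

  # idempotence: aligning an already-aligned outcome changes nothing
  al2 <- alignAlleles(al$exposure, al$outcome)
  expect_equal(summaryData(al2$outcome), od)
  expect_equal(nrow(al2$excluded), 0)
})

test_that("orientation flips all betas jointly and preserves Wald ratios", {
  inst <- data.frame(
    snp = c("rs1", "rs2", "rs3"), proxy_of = NA_character_,
    proxy_r2 = NA_real_, effect_allele = "A", other_allele = "G",
    eaf = c(0.3, 0.4, 0.5),
    beta_exposure = c(-0.03, 0.03, 0), se_exposure = 0.004,
    pvalue_exposure = 0.001,
    beta_outcome = c(0.01, 0.01, 0.02), se_outcome = 0.01,
    pvalue_outcome = 0.3, stringsAsFactors = FALSE)
  cov <- list(height = covTable(c("rs1", "rs2", "rs3"), 0.5,
                                beta = c(0.1, 0.1, 0.1), se = 0.02))
  ratioBefore <- inst$beta_outcome / inst$beta_exposure
  out <- orientToExposureIncreasing(inst, cov)
  # rs1 flipped jointly
  expect_equal(out$data$beta_exposure[out$data$snp == "rs1"], 0.03)
  expect_equal(out$data$beta_outcome[out$data$snp == "rs1"], -0.01)
  expect_equal(out$covariates$height$beta[1], -0.1)
  # rs2 untouched
  expect_equal(out$data$beta_outcome[out$data$snp == "rs2"], 0.01)
  expect_equal(out$covariates$height$beta[2], 0.1)
  # rs3 is a null instrument
  expect_equal(out$excluded$reason, "null_instrument")
  # Wald ratios unchanged for retained SNPs
  expect_equal(out$data$beta_outcome / out$data$beta_exposure,
               ratioBefore[1:2])
})

test_that("proxy substitution applies the r2 threshold", {
  d <- data.frame(snp = c("rs_proxyA", "rs_lead3"), effect_allele = "A",
                  other_allele = "G", eaf = 0.3, beta = 0.01, se = 0.005,
                  pvalue = 0.04, n = 1e5, stringsAsFactors = FALSE)
  ds <- new("SummaryStats", data = d, trait = "t",
            traitKind = "quantitative")
  pm <- data.frame(lead_snp = c("rs_lead1", "rs_lead2"),
                   proxy_snp = c("rs_proxyA", "rs_proxyA"),
                   r2 = c(0.9, 0.7), stringsAsFactors = FALSE)
  sub <- substituteProxies(c("rs_lead1", "rs_lead2", "rs_lead3"), ds, pm,
                           minR2 = 0.8)
  expect_equal(sub$used, c("rs_proxyA", NA, "rs_lead3"))
  expect_equal(sub$proxy_of, c("rs_lead1", NA, NA))
  expect_equal(sub$proxy_r2, c(0.9, NA, NA))
  # looser threshold admits the weaker proxy
  sub2 <- substituteProxies(c("rs_lead2"), ds, pm, minR2 = 0.6)
  expect_equal(sub2$used, "rs_proxyA")
})

test_that("lead/proxy accounting reproduces the 26 + 28 = 54 locus pattern", {
  # 59 leads; 26 present everywhere, 28 only via a proxy with r2 > 0.6,
  # 5 with no qualifying proxy anywhere.
  leads <- sprintf("lead%02d", 1:59)
  proxies <- sprintf("prox%02d", 27:54)
  d <- data.frame(snp = c(leads[1:26], proxies), effect_allele = "A",
                  other_allele = "G", eaf = 0.3, beta = 0.01, se = 0.005,
                  pvalue = 0.5, n = 1e5, stringsAsFactors = FALSE)
  ds <- new("SummaryStats", data = d, trait = "cov",
            traitKind = "quantitative")
  pm <- data.frame(lead_snp = leads[27:54], proxy_snp = proxies,
                   r2 = 0.85, stringsAsFactors = FALSE)
  sub <- substituteProxies(leads, ds, pm, minR2 = 0.6)
  expect_equal(sum(!is.na(sub$used)), 54)
  expect_equal(sum(is.na(sub$proxy_of) & !is.na(sub$used)), 26)
  expect_equal(sum(!is.na(sub$proxy_of)), 28)
})

test_that("harmonisation produces a valid oriented set with provenance", {
  spec <- syntheticStudySpec(nSnps = 12, seed = 11)
  sim <- generateTwoSample(spec)
  set <- harmoniseInstruments(sim$exposure, sim$outcome)
  expect_s4_class(set, "InstrumentSet")
  expect_true(all(instruments(set)$beta_exposure > 0))
  expect_equal(instruments(set)$wald_se,
               instruments(set)$se_outcome /
                 abs(instruments(set)$beta_exposure))
  expect_true(validObject(set))
})

test_that("strict palindrome mode drops ambiguous A/T and C/G SNPs", {
  mk <- function(ea, oa, eaf) data.frame(
    snp = sprintf("rs%d", seq_along(ea)), effect_allele = ea,
    other_allele = oa, eaf = eaf, beta = 0.02, se = 0.004,
    pvalue = 6e-7, n = 1e5, stringsAsFactors = FALSE)
  exposure <- new("SummaryStats",
                  data = mk(c("A", "C", "A"), c("T", "G", "G"),
                            c(0.50, 0.30, 0.50)),
                  trait = "x", traitKind = "quantitative")
  outcome <- new("SummaryStats", data = exposure@data, trait = "y",
                 traitKind = "binary")
  lax <- harmoniseInstruments(exposure, outcome)
  expect_equal(nInstruments(lax), 3)
  strict <- harmoniseInstruments(exposure, outcome,
                                 strictPalindromes = TRUE)
  # rs1 (A/T, eaf 0.5) dropped; rs2 (C/G, eaf 0.3) and rs3 (A/G) kept
  expect_equal(sort(instruments(strict)$snp), c("rs2", "rs3"))
  expect_true("palindromic_ambiguous" %in% exclusions(strict)$reason)
})

test_that("instrument tables round-trip through TSV field-for-field", {
  sim <- simulateInstrumentSet(syntheticStudySpec(nSnps = 8, seed = 3))
  tf <- tempfile(fileext = ".tsv")
  exportInstruments(sim$set, tf)
  back <- importInstruments(tf)
  expect_equal(instruments(back), instruments(sim$set), tolerance = 1e-12)
})
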