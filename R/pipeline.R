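.DEFAULT_THRESHOLDS <- list(gw_significance = 5e-8, bonferroni_alpha = 0.05,
                            proxy_r2 = 0.6, proxy_r2_mvmr = 0.8,
                            stepwise_alpha = 0.05, studentised = 2)

.ALL_METHODS <- c("ivw", "mr_egger", "weighted_median", "weighted_mode",
                  "ivw_penalised_robust")

#' Read and validate a pipeline configuration
#'
#' Configurations are YAML (or an equivalent R list) naming the dataset
#' paths and analysis settings; unspecified thresholds default to the
#' conventional values (genome-wide significance 5e-8, Bonferroni alpha
#' 0.05, proxy r2 0.6 univariable / 0.8 multivariable, stepwise alpha 0.05,
#' studentised-residual threshold 2).
#'
#' Top-level fields: \code{exposure} (path), \code{outcomes} (named list;
#' each entry a path or a list with \code{path}, \code{n_cases},
#' \code{n_controls}), \code{covariates} (named list of paths, optional),
#' \code{proxy_map} (path, optional), \code{thresholds}, \code{methods},
#' \code{mvmr_exposures} (covariate traits to include in multivariable MR),
#' \code{n_boot}, \code{seed}, \code{or_detect} (for the power report),
#' \code{output_dir} (optional).
#'
#' @param config path to a YAML file, or a list with the same structure.
#' @return the validated, default-filled configuration list.
#' @export
readRunConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  thr <- utils::modifyList(.DEFAULT_THRESHOLDS,
                           config$thresholds %||% list())
  config$thresholds <- thr
  config$methods <- config$methods %||% .ALL_METHODS
  if (length(config$methods) == 0)
    stop("config error: empty method list")
  bad <- setdiff(config$methods, .ALL_METHODS)
  if (length(bad))
    stop("config error: unknown method(s): ", paste(bad, collapse = ", "))
  config$n_boot <- config$n_boot %||% 5000
  config$seed <- as.integer(config$seed %||% 1L)
  config$or_detect <- config$or_detect %||% 1.06
  if (is.null(config$exposure)) stop("config error: no exposure dataset")
  if (is.null(config$outcomes) || !length(config$outcomes))
    stop("config error: no outcome dataset")
  config$outcomes <- lapply(config$outcomes, function(o)
    if (is.character(o)) list(path = o) else o)
  paths <- c(config$exposure,
             vapply(config$outcomes, `[[`, "", "path"),
             unlist(config$covariates), config$proxy_map)
  missing_files <- paths[!file.exists(paths)]
  if (length(missing_files))
    stop("config error: missing file(s): ",
         paste(missing_files, collapse = ", "))
  with(thr, stopifnot(gw_significance > 0, gw_significance < 1,
                      bonferroni_alpha > 0, bonferroni_alpha < 1,
                      proxy_r2 > 0, proxy_r2 <= 1,
                      proxy_r2_mvmr > 0, proxy_r2_mvmr <= 1,
                      stepwise_alpha > 0, stepwise_alpha < 1,
                      studentised > 0))
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.membershipLog <- function(stage, set, snps, action, detail = "") {
  if (!length(snps))
    return(data.frame(stage = character(), set = character(),
                      snp = character(), action = character(),
                      detail = character(), stringsAsFactors = FALSE))
  data.frame(stage = stage, set = set, snp = snps, action = action,
             detail = detail, stringsAsFactors = FALSE)
}

#' Run the full two-sample MR pipeline
#'
#' Orchestrates harmonise, instrument selection, estimation, diagnostics,
#' multivariable MR, and strength/power analytics from one configuration:
#' for each outcome, the exposure and outcome tables are harmonised (with
#' proxy substitution), three nested instrument sets are built (the full
#' harmonised set, a genome-wide pleiotropy-filtered set, and a
#' Bonferroni-filtered set), every configured estimator is run on each set,
#' the heterogeneity/influence diagnostics and a stepwise-pruned IVW are
#' computed on the genome-wide-filtered set, and multivariable MR is run
#' when covariate betas are available. The result table has one row per
#' (instrument set, method, outcome). Instrument-set membership decisions
#' are logged so each set can be reconstructed from the provenance log
#' alone. Given the same configuration (including seeds) the run is
#' deterministic.
#'
#' @param config list or YAML path (see \code{\link{readRunConfig}}).
#' @return list with \code{results} (data.frame), \code{sets},
#'   \code{diagnostics}, \code{pruned}, \code{mvmr}, \code{power},
#'   \code{enrichment}, \code{provenance} and \code{config}.
#' @export
runPipeline <- function(config) {
  config <- readRunConfig(config)
  thr <- config$thresholds
  set.seed(config$seed)
  exposure <- readSummaryStats(config$exposure, "quantitative", "exposure")
  covariates <- list()
  for (tr in names(config$covariates))
    covariates[[tr]] <- readSummaryStats(config$covariates[[tr]],
                                         "quantitative", tr)
  proxyMap <- if (!is.null(config$proxy_map))
    readProxyMap(config$proxy_map) else NULL

  results <- list()
  provenance <- list()
  sets <- list()
  diagnostics <- list()
  pruned <- list()
  mvmr <- list()
  power <- list()
  enrichment <- list()

  for (outName in names(config$outcomes)) {
    oc <- config$outcomes[[outName]]
    outcome <- readSummaryStats(oc$path, "binary", outName)
    full <- harmoniseInstruments(exposure, outcome, covariates,
                                 proxyMap, minR2 = thr$proxy_r2,
                                 name = paste0("IVfull_", outName))
    provenance[[length(provenance) + 1L]] <- rbind(
      .membershipLog("harmonise", full@name, full@data$snp, "include"),
      .membershipLog("harmonise", full@name, full@exclusions$snp,
                     "exclude", full@exclusions$reason))
    ivSets <- list(full)
    if (length(covariates)) {
      gw <- filterPleiotropic(full, thr$gw_significance,
                              name = paste0("IVgw_", outName))
      bonf <- filterPleiotropic(
        full, bonferroniThreshold(thr$bonferroni_alpha, nrow(full@data)),
        name = paste0("IVbonf_", outName))
      ivSets <- c(ivSets, list(gw, bonf))
      for (s in list(gw, bonf)) {
        rm <- unique(s@filterLog$snp[s@filterLog$action == "removed"])
        provenance[[length(provenance) + 1L]] <- rbind(
          .membershipLog("pleiotropy_filter", s@name, s@data$snp,
                         "include"),
          .membershipLog("pleiotropy_filter", s@name, rm, "exclude",
                         "covariate_association"))
      }
    }
    main <- ivSets[[min(2, length(ivSets))]]  # gw-filtered set if built
    for (s in ivSets) {
      est <- mrEstimate(s, config$methods, nBoot = config$n_boot,
                        seed = config$seed)
      results[[length(results) + 1L]] <-
        estimatesTable(est, ivSet = s@name, outcome = outName)
      sets[[s@name]] <- s
    }
    if (nrow(main@data) >= 3) {
      diagnostics[[outName]] <- influenceDiagnostics(
        main, alpha = thr$stepwise_alpha,
        studentisedThreshold = thr$studentised)
      pr <- stepwiseQPrune(main, alpha = thr$stepwise_alpha)
      pruned[[outName]] <- pr
      sets[[pr$set@name]] <- pr$set
      provenance[[length(provenance) + 1L]] <- rbind(
        .membershipLog("stepwise_prune", pr$set@name, pr$set@data$snp,
                       "include"),
        .membershipLog("stepwise_prune", pr$set@name, pr$removed,
                       "exclude", "q_contribution"))
      results[[length(results) + 1L]] <-
        estimatesTable(mrIVW(pr$set), ivSet = pr$set@name,
                       outcome = outName)
    }
    if (length(config$mvmr_exposures)) {
      mvSet <- harmoniseInstruments(exposure, outcome, covariates,
                                    proxyMap, minR2 = thr$proxy_r2_mvmr,
                                    name = paste0("IVmv_", outName))
      mvTab <- .mvTableFromSet(mvSet, config$mvmr_exposures)
      if (!is.null(mvTab) && nrow(mvTab@data) >=
          length(mvTab@exposures) + 2) {
        fitI <- mvmrIVW(mvTab)
        fitE <- mvmrEgger(mvTab)
        mvmr[[outName]] <- list(ivw = fitI, egger = fitE)
        results[[length(results) + 1L]] <-
          estimatesTable(list(fitI$exposure, fitE$exposure),
                         ivSet = mvTab@name, outcome = outName)
        provenance[[length(provenance) + 1L]] <-
          .membershipLog("mvmr", mvTab@name, mvTab@data$snp, "include")
      }
    }
    ## strength and power on the main set's exposure-side statistics
    r2 <- varianceExplainedPN(pmin(pmax(main@data$pvalue_exposure,
                                        1e-300), 1 - 1e-16),
                              n = stats::median(summaryData(exposure)$n,
                                                na.rm = TRUE))
    fs <- fStatistic(r2, stats::median(summaryData(exposure)$n,
                                       na.rm = TRUE),
                     nrow(main@data))
    power[[outName]] <- data.frame(
      outcome = outName, iv_set = main@name, n_snps = nrow(main@data),
      r2 = r2, f_statistic = as.numeric(fs), weak = attr(fs, "weak"),
      or_detect = config$or_detect,
      power = if (!is.null(oc$n_cases) && !is.null(oc$n_controls))
        binaryOutcomePower(r2, oc$n_cases, oc$n_controls,
                           config$or_detect) else NA_real_,
      stringsAsFactors = FALSE)
    enrichment[[outName]] <-
      enrichmentCount(full@data$pvalue_outcome, 0.05)
  }

  out <- list(results = do.call(rbind, results), sets = sets,
              diagnostics = diagnostics, pruned = pruned, mvmr = mvmr,
              power = do.call(rbind, power),
              enrichment = enrichment,
              provenance = do.call(rbind, provenance), config = config)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(out$results,
                       file.path(config$output_dir, "results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(out$provenance,
                       file.path(config$output_dir, "provenance.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(out$power,
                       file.path(config$output_dir, "power.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      lapply(out$diagnostics, function(dg)
        list(q = dg@q, df = dg@df, pvalue = dg@pvalue,
             flagged = dg@flagged)),
      file.path(config$output_dir, "diagnostics.json"),
      auto_unbox = TRUE, digits = NA)
  }
  out
}

## Build an MVInstrumentSet from a harmonised InstrumentSet and the chosen
## covariate traits; returns NULL when any chosen trait lacks betas.
.mvTableFromSet <- function(set, mvTraits) {
  d <- set@data
  tab <- data.frame(snp = d$snp, beta_outcome = d$beta_outcome,
                    se_outcome = d$se_outcome,
                    beta_exposure = d$beta_exposure,
                    se_exposure = d$se_exposure,
                    stringsAsFactors = FALSE)
  for (tr in mvTraits) {
    if (!tr %in% names(set@covariates)) return(NULL)
    cv <- set@covariates[[tr]]
    b <- cv$beta[match(d$snp, cv$snp)]
    s <- cv$se[match(d$snp, cv$snp)]
    if (anyNA(b) || anyNA(s)) return(NULL)   # p-only trait: not eligible
    tab[[paste0("beta_", tr)]] <- b
    tab[[paste0("se_", tr)]] <- s
  }
  makeMVInstrumentSet(tab, exposures = c("exposure", mvTraits),
                      primary = "exposure",
                      name = paste0(set@name, "_mv"))
}

#' Enrichment of outcome associations over chance expectation
#'
#' Counts instruments associated with the outcome at \code{p < alpha},
#' compares with the count expected by chance (alpha times the number of
#' SNPs) and reports the fold enrichment.
#'
#' @param pValues per-SNP outcome p-values in (0, 1].
#' @param alpha count threshold (default 0.05).
#' @return list with \code{observed}, \code{expected}, \code{fold}.
#' @examples
#' enrichmentCount(c(rep(0.01, 18), runif(41, 0.06, 1)), 0.05)
#' @export
enrichmentCount <- function(pValues, alpha = 0.05) {
  stopifnot(all(pValues > 0), all(pValues <= 1), alpha > 0, alpha <= 1)
  observed <- sum(pValues < alpha)
  expected <- alpha * length(pValues)
  list(observed = observed, expected = expected,
       fold = observed / expected)
}
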