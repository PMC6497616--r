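#' Cochran's Q heterogeneity test for an instrument set
#'
#' Measures between-instrument heterogeneity of the per-SNP Wald ratios
#' about the fixed-effects IVW estimate: Q = sum_j (ratio_j - theta)^2 /
#' wald_se_j^2, chi-square with L - 1 df under homogeneity. Per-SNP
#' contributions are returned; they are non-negative and sum to Q.
#'
#' @param set an \linkS4class{InstrumentSet} with >= 2 instruments.
#' @return a \linkS4class{HeterogeneityReport} (flag sets empty; see
#'   \code{\link{influenceDiagnostics}}).
#' @export
cochranQ <- function(set) {
  stopifnot(is(set, "InstrumentSet"))
  d <- set@data
  L <- nrow(d)
  if (L < 2) stop("Cochran's Q needs >= 2 instruments")
  theta <- .ivwCore(d$beta_exposure, d$beta_outcome, d$se_outcome)$beta
  contrib <- setNames((d$wald_ratio - theta)^2 / d$wald_se^2, d$snp)
  q <- sum(contrib)
  new("HeterogeneityReport", q = q, df = L - 1L,
      pvalue = pchisq(q, df = L - 1, lower.tail = FALSE),
      perSNP = contrib, flagged = list())
}

#' Stepwise heterogeneity pruning of an instrument set
#'
#' Greedy downward model selection: repeatedly remove the SNP with the
#' largest per-SNP Cochran's Q contribution, refitting the IVW estimate and
#' Q after each removal, until the Q test is no longer significant at
#' \code{alpha}. Q strictly decreases at every step. Ties on the largest
#' contribution are broken by lexicographic SNP id, for determinism. With
#' \code{refit = FALSE} contributions are measured against the initial
#' full-set IVW estimate throughout (the non-refitting variant); the
#' refitting variant is the default.
#'
#' @param set an \linkS4class{InstrumentSet} with >= 3 instruments.
#' @param alpha stopping significance level for the Q test (default 0.05).
#' @param refit logical; recompute the IVW estimate after each removal.
#' @return list with \code{set} (the pruned \linkS4class{InstrumentSet},
#'   renamed \code{<name>_pruned}), \code{removed} (SNP ids in removal
#'   order), \code{q_trace} (Q after each removal, starting with the full
#'   set), and \code{converged} (FALSE if pruning would have gone below 2
#'   instruments).
#' @export
stepwiseQPrune <- function(set, alpha = 0.05, refit = TRUE) {
  stopifnot(is(set, "InstrumentSet"), alpha > 0, alpha < 1)
  if (nrow(set@data) < 3) stop("stepwise pruning needs >= 3 instruments")
  current <- set
  removed <- character()
  thetaFixed <- .ivwCore(set@data$beta_exposure, set@data$beta_outcome,
                         set@data$se_outcome)$beta
  rep0 <- cochranQ(current)
  qTrace <- rep0@q
  pvalue <- rep0@pvalue
  converged <- TRUE
  while (pvalue < alpha) {
    d <- current@data
    if (nrow(d) <= 2) {
      converged <- FALSE
      break
    }
    theta <- if (refit)
      .ivwCore(d$beta_exposure, d$beta_outcome, d$se_outcome)$beta
    else thetaFixed
    contrib <- (d$wald_ratio - theta)^2 / d$wald_se^2
    worst <- order(-contrib, d$snp)[1]
    removed <- c(removed, d$snp[worst])
    current <- current[-worst]
    rep <- cochranQ(current)
    qTrace <- c(qTrace, rep@q)
    pvalue <- rep@pvalue
  }
  current@name <- paste0(set@name, "_pruned")
  list(set = current, removed = removed, q_trace = qTrace,
       converged = converged)
}

## Weighted zero-intercept IVW regression as an lm fit, the model on which
## the regression-influence diagnostics are computed.
.ivwLm <- function(set) {
  d <- set@data
  lm(beta_outcome ~ beta_exposure - 1, data = d,
     weights = 1 / d$se_outcome^2)
}

## Influence measures are 0/0 on an exact fit; treat numerically zero
## residuals as exactly zero influence.
.isExactFit <- function(fit, by) {
  max(abs(stats::residuals(fit))) < 1e-10 * max(abs(by), 1e-300)
}

#' Cook's distance influence flags for the IVW model
#'
#' Cook's distance of each instrument in the weighted zero-intercept IVW
#' regression, flagged where the distance exceeds 4 / L (L = number of
#' instruments in the set).
#'
#' @param set an \linkS4class{InstrumentSet} with >= 3 instruments.
#' @return named numeric vector of distances with attribute
#'   \code{"flagged"} (character vector of SNP ids over the threshold) and
#'   \code{"threshold"}.
#' @export
cooksInfluence <- function(set) {
  stopifnot(is(set, "InstrumentSet"))
  if (nrow(set@data) < 3) stop("Cook's distance needs >= 3 instruments")
  fit <- .ivwLm(set)
  cd <- if (.isExactFit(fit, set@data$beta_outcome))
    setNames(numeric(nrow(set@data)), set@data$snp)
  else setNames(unname(cooks.distance(fit)), set@data$snp)
  thr <- 4 / nrow(set@data)
  structure(cd, flagged = names(cd)[!is.na(cd) & cd > thr],
            threshold = thr)
}

#' Leave-one-out IVW analysis
#'
#' Repeats the IVW analysis L times, omitting each instrument in turn, and
#' once on the full set (row \code{"(all)"}): L + 1 rows of estimate, SE,
#' 95\% CI and p-value. Instruments whose omission moves the estimate far
#' from the full-set row are influential.
#'
#' @param set an \linkS4class{InstrumentSet} with >= 3 instruments.
#' @param randomEffects logical, as in \code{\link{mrIVW}}.
#' @return data.frame with columns \code{snp_removed}, \code{n_snps},
#'   \code{beta}, \code{se}, \code{ci_lower}, \code{ci_upper},
#'   \code{pvalue}.
#' @export
leaveOneOut <- function(set, randomEffects = TRUE) {
  stopifnot(is(set, "InstrumentSet"))
  L <- nrow(set@data)
  if (L < 3) stop("leave-one-out needs >= 3 instruments")
  rows <- lapply(seq_len(L), function(j) {
    e <- mrIVW(set[-j], randomEffects)
    data.frame(snp_removed = set@data$snp[j], n_snps = e@nSNPs,
               beta = e@beta, se = e@se, ci_lower = e@ciLower,
               ci_upper = e@ciUpper, pvalue = e@pvalue,
               stringsAsFactors = FALSE)
  })
  eAll <- mrIVW(set, randomEffects)
  rbind(do.call(rbind, rows),
        data.frame(snp_removed = "(all)", n_snps = eAll@nSNPs,
                   beta = eAll@beta, se = eAll@se, ci_lower = eAll@ciLower,
                   ci_upper = eAll@ciUpper, pvalue = eAll@pvalue,
                   stringsAsFactors = FALSE))
}

#' Studentised-residual outlier flags for the IVW model
#'
#' Externally studentised residuals (each residual scaled by a
#' delete-one-residual variance estimate) of the weighted zero-intercept
#' IVW regression, flagged where the absolute value exceeds
#' \code{threshold} (2 by convention).
#'
#' @param set an \linkS4class{InstrumentSet} with >= 3 instruments.
#' @param threshold absolute-residual flag threshold (default 2).
#' @return named numeric vector of studentised residuals with attribute
#'   \code{"flagged"}.
#' @export
studentisedOutliers <- function(set, threshold = 2) {
  stopifnot(is(set, "InstrumentSet"), threshold > 0)
  if (nrow(set@data) < 3)
    stop("studentised residuals need >= 3 instruments")
  fit <- .ivwLm(set)
  rs <- if (.isExactFit(fit, set@data$beta_outcome))
    setNames(numeric(nrow(set@data)), set@data$snp)
  else setNames(unname(rstudent(fit)), set@data$snp)
  structure(rs, flagged = names(rs)[!is.na(rs) & abs(rs) > threshold],
            threshold = threshold)
}

#' Full heterogeneity and influence report
#'
#' Runs Cochran's Q plus all four influence analyses (stepwise pruning,
#' Cook's distance, leave-one-out, studentised residuals) and collects the
#' flagged SNPs per method into one report. The leave-one-out flag set
#' contains the SNPs whose omission shifts the IVW estimate by more than
#' \code{looSdFactor} standard deviations of the leave-one-out estimates
#' around the full-set estimate.
#'
#' @param set an \linkS4class{InstrumentSet} with >= 3 instruments.
#' @param alpha stepwise-pruning stopping level.
#' @param studentisedThreshold threshold for \code{studentisedOutliers}.
#' @param looSdFactor leave-one-out flag factor (default 2).
#' @return a \linkS4class{HeterogeneityReport} with \code{flagged} sets
#'   \code{stepwise}, \code{cooks}, \code{loo}, \code{studentised}.
#' @export
influenceDiagnostics <- function(set, alpha = 0.05,
                                 studentisedThreshold = 2,
                                 looSdFactor = 2) {
  rep <- cochranQ(set)
  prune <- stepwiseQPrune(set, alpha = alpha)
  cd <- cooksInfluence(set)
  loo <- leaveOneOut(set)
  full <- loo$beta[loo$snp_removed == "(all)"]
  shifts <- loo$beta[loo$snp_removed != "(all)"] - full
  looFlag <- loo$snp_removed[loo$snp_removed != "(all)"][
    abs(shifts) > looSdFactor * sd(shifts)]
  st <- studentisedOutliers(set, studentisedThreshold)
  rep@flagged <- list(stepwise = prune$removed,
                      cooks = attr(cd, "flagged"),
                      loo = looFlag,
                      studentised = attr(st, "flagged"))
  rep
}
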