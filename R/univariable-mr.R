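.Z95 <- qnorm(0.975)

.newEstimate <- function(method, beta, se, pvalue, nSNPs, extras = list(),
                         ciLower = NULL, ciUpper = NULL) {
  beta <- unname(beta); se <- unname(se); pvalue <- unname(pvalue)
  if (is.null(ciLower)) ciLower <- beta - .Z95 * se
  if (is.null(ciUpper)) ciUpper <- beta + .Z95 * se
  ciLower <- unname(ciLower); ciUpper <- unname(ciUpper)
  new("MREstimate", method = method, beta = beta, se = se,
      ciLower = ciLower, ciUpper = ciUpper, pvalue = pvalue,
      nSNPs = as.integer(nSNPs), extras = extras)
}

.ivwCore <- function(bx, by, seY) {
  w <- 1 / seY^2
  beta <- sum(w * bx * by) / sum(w * bx^2)
  seFE <- sqrt(1 / sum(w * bx^2))
  q <- sum(w * (by - beta * bx)^2)
  list(beta = beta, seFE = seFE, q = q)
}

#' Inverse-variance weighted (IVW) estimator
#'
#' Combines per-SNP Wald ratios weighting by the inverse variance of the
#' SNP-outcome associations; algebraically the zero-intercept weighted
#' regression of outcome betas on exposure betas with weights 1/se_outcome^2
#' (equivalent to two-stage least squares on individual-level data). The
#' fixed-effects SE is (sum w * bx^2)^(-1/2); under the multiplicative
#' random-effects model it is inflated by max(1, sqrt(Q / (L - 1))) where Q
#' is Cochran's Q, so the random-effects SE is never below the fixed-effects
#' one. A single instrument degrades to its Wald ratio.
#'
#' @param set an \linkS4class{InstrumentSet}.
#' @param randomEffects logical; apply the multiplicative random-effects SE
#'   inflation (default TRUE, the primary-analysis convention).
#' @return an \linkS4class{MREstimate}; \code{extras} carries
#'   \code{re_scale_factor}, \code{q} and \code{n_snps}.
#' @export
mrIVW <- function(set, randomEffects = TRUE) {
  stopifnot(is(set, "InstrumentSet"))
  d <- set@data
  L <- nrow(d)
  if (L < 1) stop("IVW requires at least one instrument")
  if (L == 1L) {
    beta <- d$wald_ratio
    se <- d$wald_se
    return(.newEstimate("IVW", beta, se, 2 * pnorm(-abs(beta / se)), 1L,
                        list(re_scale_factor = 1, q = 0, n_snps = 1L)))
  }
  fit <- .ivwCore(d$beta_exposure, d$beta_outcome, d$se_outcome)
  scale <- if (randomEffects) max(1, sqrt(fit$q / (L - 1))) else 1
  se <- fit$seFE * scale
  .newEstimate("IVW", fit$beta, se, 2 * pnorm(-abs(fit$beta / se)), L,
               list(re_scale_factor = scale, q = fit$q, n_snps = L))
}

#' MR-Egger regression
#'
#' Weighted regression of outcome betas on exposure betas with a free
#' intercept (weights 1/se_outcome^2), with all instruments oriented to the
#' exposure-increasing allele. The slope is the causal estimate, consistent
#' under the InSIDE assumption even when all instruments are pleiotropic;
#' the intercept estimates the average directional pleiotropic effect, and
#' its two-sided test (t distribution, L - 2 df) is the Egger intercept
#' test. Random-effects SE scaling uses the weighted residual sum of squares
#' on L - 2 df, floored at 1.
#'
#' @param set an \linkS4class{InstrumentSet} with at least 3 instruments.
#' @param randomEffects logical, as in \code{\link{mrIVW}}.
#' @param ciDist \code{"normal"} (default) or \code{"t"} critical values for
#'   the slope confidence interval.
#' @return an \linkS4class{MREstimate}; \code{extras} carries
#'   \code{egger_intercept}, \code{egger_intercept_se},
#'   \code{egger_intercept_p}, \code{re_scale_factor}, \code{n_snps}.
#' @export
mrEgger <- function(set, randomEffects = TRUE,
                    ciDist = c("normal", "t")) {
  stopifnot(is(set, "InstrumentSet"))
  ciDist <- match.arg(ciDist)
  d <- set@data
  L <- nrow(d)
  if (L < 3) stop("egger_underdetermined: MR-Egger needs >= 3 instruments")
  flip <- sign(d$beta_exposure)          # defensive; class enforces > 0
  bx <- d$beta_exposure * flip
  by <- d$beta_outcome * flip
  w <- 1 / d$se_outcome^2
  X <- cbind(intercept = 1, slope = bx)
  XtWX <- crossprod(X, w * X)
  cf <- solve(XtWX, crossprod(X, w * by))[, 1]
  rss <- sum(w * (by - X %*% cf)^2)
  sigma <- sqrt(rss / (L - 2))
  seUnit <- sqrt(diag(solve(XtWX)))
  scale <- if (randomEffects) max(1, sigma) else 1
  se <- seUnit * scale
  tstat <- cf / se
  p <- 2 * pt(-abs(tstat), df = L - 2)
  crit <- if (ciDist == "t") stats::qt(0.975, df = L - 2) else .Z95
  .newEstimate("MR_Egger", cf["slope"], se["slope"], p["slope"], L,
               list(egger_intercept = unname(cf["intercept"]),
                    egger_intercept_se = unname(se["intercept"]),
                    egger_intercept_p = unname(p["intercept"]),
                    re_scale_factor = scale, q_egger = rss, n_snps = L),
               ciLower = unname(cf["slope"] - crit * se["slope"]),
               ciUpper = unname(cf["slope"] + crit * se["slope"]))
}

## Weighted median by linear interpolation of the cumulative weight
## midpoints: p_j = cumsum(w)_j - w_j / 2 on the ratio order statistics.
.weightedMedian <- function(r, w) {
  ord <- order(r)
  r <- r[ord]
  w <- w[ord] / sum(w)
  cum <- cumsum(w) - w / 2
  if (0.5 <= cum[1]) return(r[1])
  if (0.5 >= cum[length(cum)]) return(r[length(r)])
  approx(cum, r, xout = 0.5, ties = "ordered")$y
}

.bootstrapSE <- function(d, statistic, nBoot, seed) {
  if (nBoot <= 0) return(NA_real_)
  if (!is.null(seed)) set.seed(seed)
  L <- nrow(d)
  ests <- vapply(seq_len(nBoot), function(b) {
    bx <- rnorm(L, d$beta_exposure, d$se_exposure)
    by <- rnorm(L, d$beta_outcome, d$se_outcome)
    statistic(by / bx, (bx / d$se_outcome)^2)
  }, numeric(1))
  sd(ests)
}

#' Weighted median estimator
#'
#' Orders the per-SNP Wald ratios, assigns each the inverse-variance weight
#' of its ratio (1/wald_se^2, normalised), and linearly interpolates the
#' ratio as a function of the cumulative weight midpoint at 50\%. Consistent
#' when over half the total weight comes from valid instruments. The SE is
#' estimated by parametric bootstrap: exposure and outcome betas are
#' resampled from normal distributions with their reported SEs and the
#' estimator recomputed.
#'
#' @param set an \linkS4class{InstrumentSet} with >= 2 instruments.
#' @param nBoot bootstrap replicates for the SE (default 5000; 0 skips the
#'   bootstrap and returns an NA SE, for simulation studies that only need
#'   the point estimate).
#' @param seed optional integer seed for the bootstrap.
#' @return an \linkS4class{MREstimate}.
#' @export
mrWeightedMedian <- function(set, nBoot = 5000, seed = NULL) {
  stopifnot(is(set, "InstrumentSet"))
  d <- set@data
  if (nrow(d) < 2) stop("weighted median needs >= 2 instruments")
  beta <- .weightedMedian(d$wald_ratio, 1 / d$wald_se^2)
  se <- .bootstrapSE(d, .weightedMedian, nBoot, seed)
  p <- if (is.na(se)) NA_real_ else 2 * pnorm(-abs(beta / se))
  .newEstimate("weighted_median", beta, se, p, nrow(d),
               list(n_boot = nBoot, n_snps = nrow(d)),
               ciLower = if (is.na(se)) NA_real_ else beta - .Z95 * se,
               ciUpper = if (is.na(se)) NA_real_ else beta + .Z95 * se)
}

## Modified Silverman bandwidth on the Wald ratios; mad() falls back to
## sd() when the median absolute deviation degenerates to zero.
.modeBandwidth <- function(r, factor) {
  s <- min(sd(r), mad(r))
  if (s == 0) s <- sd(r)
  factor * 0.9 * s * length(r)^(-1 / 5)
}

.weightedModeEstimate <- function(r, w, bandwidthFactor, gridSize) {
  w <- w / sum(w)
  h <- .modeBandwidth(r, bandwidthFactor)
  if (!is.finite(h) || h == 0) return(r[1])   # all ratios identical
  grid <- seq(min(r) - 3 * h, max(r) + 3 * h, length.out = gridSize)
  dens <- vapply(grid, function(x) sum(w * dnorm(x, mean = r, sd = h)),
                 numeric(1))
  grid[which.max(dens)]
}

#' Weighted mode estimator
#'
#' Forms a kernel-smoothed weighted density of the per-SNP Wald ratios
#' (normal kernel; bandwidth = \code{bandwidthFactor} times the modified
#' Silverman rule 0.9 min(sd, mad) L^(-1/5) on the ratios) and takes the
#' density's argmax over a fixed grid of \code{gridSize} points spanning
#' range(ratios) +/- 3 bandwidths. Consistent when the largest group of
#' SNPs with similar Wald ratios are valid instruments. Bootstrap SE as in
#' \code{\link{mrWeightedMedian}}. If all ratios coincide (zero bandwidth)
#' the common ratio is returned.
#'
#' @param set an \linkS4class{InstrumentSet} with >= 3 instruments.
#' @param bandwidthFactor multiplier on the Silverman bandwidth (default 1).
#' @param nBoot,seed bootstrap settings as in \code{\link{mrWeightedMedian}}.
#' @param gridSize density-grid resolution (default 2048).
#' @return an \linkS4class{MREstimate}.
#' @export
mrWeightedMode <- function(set, bandwidthFactor = 1, nBoot = 5000,
                           seed = NULL, gridSize = 2048) {
  stopifnot(is(set, "InstrumentSet"))
  d <- set@data
  if (nrow(d) < 3) stop("weighted mode needs >= 3 instruments")
  beta <- .weightedModeEstimate(d$wald_ratio, 1 / d$wald_se^2,
                                bandwidthFactor, gridSize)
  se <- .bootstrapSE(d, function(r, w)
    .weightedModeEstimate(r, w, bandwidthFactor, gridSize), nBoot, seed)
  p <- if (is.na(se)) NA_real_ else 2 * pnorm(-abs(beta / se))
  .newEstimate("weighted_mode", beta, se, p, nrow(d),
               list(bandwidth = .modeBandwidth(d$wald_ratio,
                                               bandwidthFactor),
                    n_boot = nBoot, n_snps = nrow(d)),
               ciLower = if (is.na(se)) NA_real_ else beta - .Z95 * se,
               ciUpper = if (is.na(se)) NA_real_ else beta + .Z95 * se)
}

#' Penalised robust IVW estimator
#'
#' Downweights instruments with outlying Wald ratios, then fits a
#' bounded-influence robust regression. Stage one computes each SNP's
#' heterogeneity tail probability p_j from its Cochran's Q contribution
#' against a 1-df chi-square and sets the penalised weight
#' w_j * min(1, p_j / penaltyAlpha) (multiplier 20 at the default alpha of
#' 0.05), so SNPs compatible with the pooled estimate keep their full
#' weight. Stage two fits a zero-intercept MM regression with Tukey
#' bisquare loss (tuning constant 4.685, 95\% efficiency under normality)
#' of outcome betas on exposure betas under those weights. The reported SE
#' is the robust-fit SE floored at the fixed-effects IVW SE under the
#' penalised weights. If every residual is numerically zero the robust fit
#' coincides with weighted least squares and is returned directly; if the
#' robust fit fails to converge, the penalised (non-robust) IVW estimate is
#' returned with a warning.
#'
#' @param set an \linkS4class{InstrumentSet} with >= 2 instruments.
#' @param penaltyAlpha penalisation level (default 0.05).
#' @return an \linkS4class{MREstimate}; \code{extras} carries
#'   \code{n_penalised}, the number of SNPs whose weight was reduced.
#' @export
mrPenalisedRobustIVW <- function(set, penaltyAlpha = 0.05) {
  stopifnot(is(set, "InstrumentSet"), penaltyAlpha > 0, penaltyAlpha < 1)
  d <- set@data
  L <- nrow(d)
  if (L < 2) stop("penalised robust IVW needs >= 2 instruments")
  bx <- d$beta_exposure
  by <- d$beta_outcome
  w <- 1 / d$se_outcome^2
  theta0 <- .ivwCore(bx, by, d$se_outcome)$beta
  qj <- (d$wald_ratio - theta0)^2 / d$wald_se^2
  pj <- pchisq(qj, df = 1, lower.tail = FALSE)
  penw <- w * pmin(1, pj / penaltyAlpha)
  ## penalised weighted-least-squares solution (the fallback and the floor)
  betaWLS <- sum(penw * bx * by) / sum(penw * bx^2)
  seFloor <- sqrt(1 / sum(penw * bx^2))
  resid <- by - betaWLS * bx
  extras <- list(n_penalised = sum(pj < penaltyAlpha), n_snps = L)
  if (max(abs(resid)) < 1e-12 * max(abs(by), 1e-300)) {
    beta <- betaWLS
    se <- seFloor
  } else {
    fit <- tryCatch(
      MASS::rlm(by ~ bx - 1, weights = penw, wt.method = "inv.var",
                psi = MASS::psi.bisquare, c = 4.685, maxit = 500,
                method = "MM"),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) {
      warning("robust fit did not converge; falling back to penalised IVW")
      beta <- betaWLS
      se <- seFloor
      extras$robust_converged <- FALSE
    } else {
      beta <- unname(coef(fit)[1])
      seRob <- tryCatch(summary(fit)$coefficients[1, "Std. Error"],
                        error = function(e) NA_real_)
      se <- max(seRob, seFloor, na.rm = TRUE)
      extras$robust_converged <- TRUE
    }
  }
  .newEstimate("IVW_penalised_robust", beta, se,
               2 * pnorm(-abs(beta / se)), L, extras)
}

#' Run a panel of univariable MR estimators
#'
#' @param set an \linkS4class{InstrumentSet}.
#' @param methods subset of \code{c("ivw", "mr_egger", "weighted_median",
#'   "weighted_mode", "ivw_penalised_robust")}.
#' @param randomEffects logical for IVW/Egger.
#' @param nBoot,seed bootstrap settings for median/mode.
#' @return named list of \linkS4class{MREstimate} objects.
#' @export
mrEstimate <- function(set,
                       methods = c("ivw", "mr_egger", "weighted_median",
                                   "weighted_mode",
                                   "ivw_penalised_robust"),
                       randomEffects = TRUE, nBoot = 5000, seed = NULL) {
  methods <- match.arg(methods, several.ok = TRUE)
  out <- list()
  for (m in methods)
    out[[m]] <- switch(m,
      ivw = mrIVW(set, randomEffects),
      mr_egger = mrEgger(set, randomEffects),
      weighted_median = mrWeightedMedian(set, nBoot, seed),
      weighted_mode = mrWeightedMode(set, nBoot = nBoot, seed = seed),
      ivw_penalised_robust = mrPenalisedRobustIVW(set))
  out
}

#' Tabulate MR estimates
#'
#' Flattens a list of \linkS4class{MREstimate} objects into one row per
#' estimate, with log-odds and odds-ratio scales side by side: the
#' machine-readable analogue of a forest plot.
#'
#' @param estimates list of \linkS4class{MREstimate}, or a single estimate.
#' @param ivSet,outcome optional labels recycled across rows.
#' @return data.frame.
#' @export
estimatesTable <- function(estimates, ivSet = NA_character_,
                           outcome = NA_character_) {
  if (is(estimates, "MREstimate")) estimates <- list(estimates)
  do.call(rbind, lapply(estimates, function(e) data.frame(
    iv_set = ivSet, outcome = outcome, method = e@method,
    n_snps = e@nSNPs, beta = e@beta, se = e@se,
    ci_lower = e@ciLower, ci_upper = e@ciUpper, pvalue = e@pvalue,
    or = exp(e@beta), or_lower = exp(e@ciLower), or_upper = exp(e@ciUpper),
    stringsAsFactors = FALSE)))
}
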