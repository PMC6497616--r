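#' Construct a multivariable instrument table
#'
#' Assembles per-SNP outcome betas/SEs and the betas/SEs of K exposure
#' traits into an \linkS4class{MVInstrumentSet}. Rows must be oriented to
#' the primary exposure-increasing allele; rows with a negative primary
#' exposure beta are flipped jointly (all exposure betas and the outcome
#' beta change sign).
#'
#' @param data data.frame with columns \code{snp}, \code{beta_outcome},
#'   \code{se_outcome}, and \code{beta_<exposure>}/\code{se_<exposure>} for
#'   each exposure.
#' @param exposures character vector of exposure names (column suffixes).
#' @param primary the exposure of interest (default: first).
#' @param name set label.
#' @return an \linkS4class{MVInstrumentSet}.
#' @export
makeMVInstrumentSet <- function(data, exposures, primary = exposures[1],
                                name = "MVIV") {
  betaCols <- paste0("beta_", exposures)
  flip <- data[[paste0("beta_", primary)]] < 0
  if (any(flip)) {
    for (cl in c(betaCols, "beta_outcome"))
      data[[cl]][flip] <- -data[[cl]][flip]
  }
  rownames(data) <- NULL
  new("MVInstrumentSet", name = name, data = data,
      exposures = exposures, primary = primary)
}

## Design matrix of exposure betas; stops naming collinear columns when the
## weighted design is rank deficient.
.mvDesign <- function(table, intercept = FALSE) {
  d <- table@data
  X <- as.matrix(d[, paste0("beta_", table@exposures), drop = FALSE])
  colnames(X) <- table@exposures
  if (intercept) X <- cbind(`(intercept)` = 1, X)
  w <- 1 / d$se_outcome^2
  qrX <- qr(sqrt(w) * X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[seq(qrX$rank + 1, ncol(X))]]
    stop("rank-deficient multivariable design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  list(X = X, w = w, by = d$beta_outcome)
}

.mvFit <- function(table, intercept, randomEffects) {
  des <- .mvDesign(table, intercept)
  L <- nrow(des$X)
  k <- ncol(des$X)
  XtWX <- crossprod(des$X, des$w * des$X)
  cf <- solve(XtWX, crossprod(des$X, des$w * des$by))[, 1]
  rss <- sum(des$w * (des$by - des$X %*% cf)^2)
  df <- L - k
  sigma <- sqrt(rss / df)
  scale <- if (randomEffects) max(1, sigma) else 1
  se <- sqrt(diag(solve(XtWX))) * scale
  list(cf = cf, se = se, df = df, scale = scale, L = L, rss = rss)
}

#' Multivariable IVW Mendelian randomisation
#'
#' Regresses per-SNP outcome betas jointly on the betas of K exposures
#' (no intercept), weighting by the inverse variance of the outcome
#' associations, with multiplicative random-effects SE scaling (residual
#' scale floored at 1) applied to every coefficient. Each exposure's
#' coefficient estimates its direct effect on the outcome holding the other
#' exposures fixed; the primary exposure's coefficient is the headline
#' estimate. With K = 1 exposure the model is identical to univariable
#' \code{\link{mrIVW}} on the same rows.
#'
#' @param table an \linkS4class{MVInstrumentSet} with at least K + 1 rows.
#' @param randomEffects logical (default TRUE).
#' @return named list of \linkS4class{MREstimate}, one per exposure;
#'   \code{extras} carries \code{re_scale_factor}, \code{n_snps} and
#'   \code{is_primary}.
#' @export
mvmrIVW <- function(table, randomEffects = TRUE) {
  stopifnot(is(table, "MVInstrumentSet"))
  K <- length(table@exposures)
  if (nrow(table@data) < K + 1)
    stop("multivariable IVW needs at least K + 1 = ", K + 1, " SNPs")
  fit <- .mvFit(table, intercept = FALSE, randomEffects = randomEffects)
  out <- lapply(table@exposures, function(ex) {
    b <- unname(fit$cf[ex]); s <- unname(fit$se[ex])
    .newEstimate("MVMR_IVW", b, s, 2 * pnorm(-abs(b / s)), fit$L,
                 list(re_scale_factor = fit$scale, n_snps = fit$L,
                      is_primary = identical(ex, table@primary)))
  })
  setNames(out, table@exposures)
}

#' Multivariable MR-Egger regression
#'
#' As \code{\link{mvmrIVW}} with a free intercept, rows oriented to the
#' primary exposure-increasing allele. The intercept estimates the average
#' directional pleiotropic effect not mediated through any included
#' exposure; its SE and two-sided p-value use a t distribution on
#' L - K - 1 df and are attached to every returned estimate's
#' \code{extras}.
#'
#' @param table an \linkS4class{MVInstrumentSet} with at least K + 2 rows.
#' @param randomEffects logical (default TRUE).
#' @return named list of \linkS4class{MREstimate}, one per exposure.
#' @export
mvmrEgger <- function(table, randomEffects = TRUE) {
  stopifnot(is(table, "MVInstrumentSet"))
  K <- length(table@exposures)
  if (nrow(table@data) < K + 2)
    stop("multivariable MR-Egger needs at least K + 2 = ", K + 2, " SNPs")
  fit <- .mvFit(table, intercept = TRUE, randomEffects = randomEffects)
  ic <- unname(fit$cf["(intercept)"])
  icSE <- unname(fit$se["(intercept)"])
  icP <- 2 * pt(-abs(ic / icSE), df = fit$df)
  out <- lapply(table@exposures, function(ex) {
    b <- unname(fit$cf[ex]); s <- unname(fit$se[ex])
    .newEstimate("MVMR_Egger", b, s, 2 * pt(-abs(b / s), df = fit$df),
                 fit$L,
                 list(egger_intercept = ic, egger_intercept_se = icSE,
                      egger_intercept_p = icP,
                      re_scale_factor = fit$scale, n_snps = fit$L,
                      is_primary = identical(ex, table@primary)))
  })
  setNames(out, table@exposures)
}
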