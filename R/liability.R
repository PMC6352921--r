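# variance multiplier from the observed 0/1 scale to the liability
# scale: c = K^2 (1-K)^2 / (P (1-P) z^2), z = phi(Phi^-1(1-K))
liabilityMultiplier <- function(prevalence, caseProportion = prevalence) {
  K <- prevalence; P <- caseProportion
  if (K <= 0 || K >= 1 || P <= 0 || P >= 1)
    stop("prevalence and case proportion must lie in (0, 1)")
  z <- dnorm(qnorm(1 - K))
  K^2 * (1 - K)^2 / (P * (1 - P) * z^2)
}

#' Observed-scale to liability-scale conversion of heritability
#'
#' Transforms a variance fraction estimated on the observed 0/1 scale
#' of a case-control trait to the underlying liability scale, using the
#' threshold-model multiplier
#' \deqn{c = \frac{K^2 (1-K)^2}{P(1-P)\, z^2}}
#' where \eqn{K} is the population prevalence, \eqn{P} the sample case
#' proportion and \eqn{z} the standard normal density at the
#' \eqn{K}-threshold.  Both the estimate and its standard error are
#' multiplied by \eqn{c}.  At \eqn{K = P = 0.5} the multiplier is
#' \eqn{\pi/2}.
#'
#' @param h2Obs,seObs observed-scale estimate and standard error.
#' @param prevalence population prevalence \eqn{K} in (0, 1).
#' @param caseProportion sample case fraction \eqn{P} (defaults to
#'   \code{prevalence}).
#' @return list with \code{h2}, \code{se} and the \code{multiplier}.
#' @seealso [liabilityInverse()], [liabilityBeta()]
#' @examples
#' liabilityTransform(0.1, 0.05, prevalence = 0.162)
#' @export
liabilityTransform <- function(h2Obs, seObs = NA_real_, prevalence,
                               caseProportion = prevalence) {
  cc <- liabilityMultiplier(prevalence, caseProportion)
  list(h2 = h2Obs * cc, se = seObs * cc, multiplier = cc)
}

#' Liability-scale to observed-scale conversion
#'
#' Exact inverse of [liabilityTransform()] (division by the same
#' multiplier), used e.g. to express a liability-scale heritability on
#' the observed case-control scale for power calculations.
#'
#' @inheritParams liabilityTransform
#' @param h2Liab,seLiab liability-scale estimate and standard error.
#' @return list with \code{h2}, \code{se} and the \code{multiplier}.
#' @export
liabilityInverse <- function(h2Liab, seLiab = NA_real_, prevalence,
                             caseProportion = prevalence) {
  cc <- liabilityMultiplier(prevalence, caseProportion)
  list(h2 = h2Liab / cc, se = seLiab / cc, multiplier = cc)
}

#' Liability-scale conversion of a regression coefficient
#'
#' First-order (Taylor-series) conversion of a fixed-effect estimate
#' and its standard error from the linear model on a 0/1 outcome to the
#' liability scale: both are multiplied by the square root of the
#' variance multiplier of [liabilityTransform()].
#'
#' @param beta,se linear-scale coefficient and standard error.
#' @inheritParams liabilityTransform
#' @return list with \code{beta}, \code{se} and the \code{multiplier}
#'   applied (the square root of the variance-scale factor).
#' @export
liabilityBeta <- function(beta, se = NA_real_, prevalence,
                          caseProportion = prevalence) {
  sc <- sqrt(liabilityMultiplier(prevalence, caseProportion))
  list(beta = beta * sc, se = se * sc, multiplier = sc)
}

#' Power of a GREML design to detect SNP heritability
#'
#' Non-centrality-parameter power calculation for variance-component
#' estimation from a genomic relationship matrix.  For a quantitative
#' design the sampling standard error is
#' \eqn{SE(\hat h^2) = \sqrt{2 / (n^2 \, \mathrm{var}_\pi)}} with
#' \eqn{\mathrm{var}_\pi} the variance of off-diagonal relatedness
#' (2e-5 for unrelated samples); the non-centrality parameter is
#' \eqn{(h^2 / SE)^2} and power is the upper tail of the non-central
#' \eqn{\chi^2_1} beyond the \eqn{\alpha} critical value.  For a
#' case-control design the liability-scale heritability is first moved
#' to the observed scale via [liabilityInverse()] with the given
#' prevalence and case proportion, and \eqn{n} is the total genotyped
#' sample size.
#'
#' @param n sample size; for case-control either the total or
#'   \code{c(nCase, nControl)}.
#' @param h2 heritability to detect (liability scale when
#'   \code{prevalence} is given).
#' @param varPi variance of off-diagonal GRM entries (default 2e-5).
#' @param alpha test size (default 0.05).
#' @param prevalence population prevalence; supplying it switches to
#'   the case-control design.
#' @param caseProportion sample case fraction; defaults to
#'   \code{n[1]/sum(n)} when \code{n} has two entries, else to
#'   \code{prevalence}.
#' @param nGenotyped optional genotyped subsample size used for the
#'   standard error in the case-control design (defaults to
#'   \code{sum(n)}).
#' @return list with \code{power}, \code{ncp}, \code{se} and
#'   \code{h2Observed}.
#' @examples
#' gremlPower(n = c(1506, 7667), h2 = 0.12, prevalence = 0.162,
#'            nGenotyped = 8734)$power  # ~ 0.32
#' @export
gremlPower <- function(n, h2, varPi = 2e-5, alpha = 0.05,
                       prevalence = NULL, caseProportion = NULL,
                       nGenotyped = NULL) {
  if (h2 < 0 || h2 > 1) stop("h2 must lie in [0, 1]")
  if (!is.null(prevalence)) {
    if (is.null(caseProportion))
      caseProportion <- if (length(n) == 2) n[1] / sum(n) else prevalence
    h2o <- liabilityInverse(h2, prevalence = prevalence,
                            caseProportion = caseProportion)$h2
    ntot <- if (is.null(nGenotyped)) sum(n) else nGenotyped
  } else {
    h2o <- h2
    ntot <- sum(n)
  }
  se <- sqrt(2 / (ntot^2 * varPi))
  ncp <- (h2o / se)^2
  crit <- qchisq(1 - alpha, 1)
  list(power = pchisq(crit, 1, ncp = ncp, lower.tail = FALSE),
       ncp = ncp, se = se, h2Observed = h2o)
}
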