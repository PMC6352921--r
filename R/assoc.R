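#' Standardise a variable
#'
#' Optionally applies \code{log1p} (suitable for count variables with
#' zeros) and then centres and scales to unit standard deviation, so
#' downstream regression coefficients are in standard-deviation units.
#' Standardising an already standardised vector returns it unchanged.
#'
#' @param values numeric vector.
#' @param logTransform apply \code{log1p} first.
#' @return standardised vector.
#' @export
standardise <- function(values, logTransform = FALSE) {
  if (logTransform) values <- log1p(values)
  s <- sd(values, na.rm = TRUE)
  if (!is.finite(s) || s == 0)
    stop("cannot standardise a constant (zero-variance) vector")
  (values - mean(values, na.rm = TRUE)) / s
}

#' Prevalence of a binary trait
#'
#' Cases over cases plus controls; missing status is excluded.
#'
#' @param status binary 0/1 vector (NA allowed), or the number of
#'   cases when \code{controls} is given.
#' @param controls optional number of controls (counts interface).
#' @return fraction of cases.
#' @examples
#' prevalence(1506, 7667)  # 0.164
#' @export
prevalence <- function(status, controls = NULL) {
  if (!is.null(controls)) return(status / (status + controls))
  status <- status[!is.na(status)]
  mean(status)
}

#' Relative risk from a 2x2 exposure table
#'
#' \eqn{RR = (a/n_1) / (c/n_0)} with the Wald confidence interval
#' \eqn{\exp(\ln RR \pm z_{\alpha/2}
#'   \sqrt{1/a - 1/n_1 + 1/c - 1/n_0})}.
#'
#' @param exposedCases,exposedN cases and total among the exposed.
#' @param unexposedCases,unexposedN cases and total among the
#'   unexposed.
#' @param conf confidence level (default 0.95).
#' @param continuity add 0.5 to all cells (required when a cell is 0).
#' @return list with \code{rr}, \code{ciLow}, \code{ciHigh},
#'   \code{table} (the 2x2 counts).
#' @examples
#' relativeRisk(30, 100, 20, 100)  # RR 1.5, CI (0.916, 2.456)
#' @export
relativeRisk <- function(exposedCases, exposedN, unexposedCases,
                         unexposedN, conf = 0.95, continuity = FALSE) {
  a <- exposedCases; n1 <- exposedN
  c0 <- unexposedCases; n0 <- unexposedN
  if (any(c(a, n1 - a, c0, n0 - c0) < 0))
    stop("inconsistent 2x2 counts")
  if (!continuity && (a == 0 || c0 == 0 || a == n1 || c0 == n0))
    stop("zero cell in the 2x2 table; set continuity = TRUE ",
         "to add 0.5 to all cells")
  if (continuity) {
    a <- a + 0.5; c0 <- c0 + 0.5; n1 <- n1 + 1; n0 <- n0 + 1
  }
  rr <- (a / n1) / (c0 / n0)
  sel <- sqrt(1 / a - 1 / n1 + 1 / c0 - 1 / n0)
  zc <- qnorm(1 - (1 - conf) / 2)
  list(rr = rr, ciLow = rr * exp(-zc * sel), ciHigh = rr * exp(zc * sel),
       table = matrix(c(exposedCases, exposedN - exposedCases,
                        unexposedCases, unexposedN - unexposedCases),
                      2, 2, dimnames = list(c("case", "noncase"),
                                            c("exposed", "unexposed"))))
}

#' Mixed-model association between two traits
#'
#' Tests the association of predictor \code{x} with outcome \code{y}
#' given covariates, controlling for family structure via a pedigree
#' random effect — the same machinery as [prsAssoc()], reused for
#' phenotype-phenotype tests.  For a binary outcome the coefficient and
#' standard error are additionally reported on the liability scale.
#'
#' @param y outcome vector (0/1 allowed when \code{binary = TRUE}).
#' @param x predictor (standardised internally).
#' @param X covariate matrix.
#' @param K pedigree [RelationshipMatrix-class]; NULL reduces to OLS.
#' @param binary treat \code{y} as a case-control outcome.
#' @param prevalenceK population prevalence for the liability
#'   conversion (defaults to the sample case fraction).
#' @return list with \code{beta}, \code{se}, \code{r2}, \code{p}, and
#'   for binary outcomes \code{betaLiability}, \code{seLiability}.
#' @export
traitAssoc <- function(y, x, X = NULL, K = NULL, binary = FALSE,
                       prevalenceK = NULL) {
  res <- prsAssoc(y, x, X, K)
  if (binary) {
    P <- mean(y, na.rm = TRUE)
    Kpop <- if (is.null(prevalenceK)) P else prevalenceK
    lb <- liabilityBeta(res$beta, res$se, prevalence = Kpop,
                        caseProportion = P)
    res$betaLiability <- lb$beta
    res$seLiability <- lb$se
  }
  res
}
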