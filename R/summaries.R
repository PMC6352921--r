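#' Narrow-sense heritability from a variance decomposition
#'
#' In a family-based decomposition the narrow-sense heritability is the
#' sum of the SNP-genetic (G) and residual pedigree-genetic (K)
#' fractions, shared environment being modelled separately.
#'
#' @param fit a [VarianceFit-class], or a named numeric vector of
#'   variance fractions.
#' @return sum of the available G and K fractions.
#' @examples
#' narrowSenseHeritability(c(G = 0.07, K = 0.06, C = 0.14))  # 0.13
#' @export
narrowSenseHeritability <- function(fit) {
  est <- if (is(fit, "VarianceFit")) estimates(fit) else fit
  sum(est[names(est) %in% c("G", "K")])
}

#' Unexplained phenotypic variance of a variance decomposition
#'
#' The fraction of phenotypic variance assigned to none of the fitted
#' genetic or shared-environment components, i.e. 1 minus their sum
#' (equivalently the residual fraction).
#'
#' @inheritParams narrowSenseHeritability
#' @return residual fraction in [0, 1].
#' @examples
#' unexplainedVariance(c(G = 0.08, C = 0.13))  # 0.79
#' @export
unexplainedVariance <- function(fit) {
  est <- if (is(fit, "VarianceFit")) estimates(fit) else fit
  if ("E" %in% names(est)) return(unname(est[["E"]]))
  1 - sum(est)
}
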