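#' Backward stepwise selection of variance components
#'
#' Starts from the full model containing every supplied relationship
#' matrix (canonically G, K, F, C, S) and iteratively removes
#' components: a component is a removal candidate if it fails to reach
#' significance at \code{alpha} in \emph{both} the Wald and the
#' likelihood-ratio test, and among candidates the one with the largest
#' Wald p-value is removed.  The procedure stops when every remaining
#' component is significant in at least one of the two tests; an empty
#' final model is a legal outcome.
#'
#' @param y,X,matrices as in [remlFit()].
#' @param alpha significance level (default 0.05).
#' @param ... further arguments passed to [remlFit()].
#' @return list with \code{final} (character vector of retained
#'   component labels), \code{fit} (the final [VarianceFit-class]) and
#'   \code{trace} (list of the fit at each elimination step, each with
#'   both tests filled in).
#' @export
stepwiseSelect <- function(y, X = NULL, matrices, alpha = 0.05, ...) {
  current <- matrices
  trace <- list()
  fit <- remlFit(y, X, current, lrt = TRUE, ...)
  repeat {
    trace[[length(trace) + 1]] <- fit
    labels <- setdiff(names(fit@estimates), "E")
    if (length(labels) == 0) break
    wald <- fit@waldP[labels]
    lrtp <- fit@lrtP[labels]
    candidates <- which(wald > alpha & lrtp > alpha)
    if (length(candidates) == 0) break
    dropIdx <- candidates[which.max(wald[candidates])]
    current <- current[-dropIdx]
    fit <- remlFit(y, X, current, lrt = TRUE, ...)
  }
  list(final = setdiff(names(fit@estimates), "E"), fit = fit,
       trace = trace)
}
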