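#' REML estimation of genetic and environmental variance components
#'
#' Fits the linear mixed model \eqn{y = Xb + \sum_i u_i + e} with
#' \eqn{u_i \sim N(0, \sigma^2_i A_i)} for an arbitrary set of
#' relationship matrices (G, K, F, C, S) by restricted maximum
#' likelihood.  The maximiser takes one expectation-maximisation step
#' followed by average-information (AI) updates, reverting to an EM
#' step whenever an AI step decreases the restricted likelihood.
#' Convergence is declared when successive log-likelihood change falls
#' below \code{tol}.  With \code{constrainNonnegative = TRUE} components
#' stepping below zero are pinned just above it; if a pinned constrained
#' fit fails to converge, an unconstrained refit is performed and
#' flagged via the \code{constrained} slot.
#'
#' Components are reported as fractions of the total phenotypic
#' variance with delta-method standard errors from the inverse AI
#' matrix; per-component Wald p-values are two-sided
#' \eqn{\chi^2_1} tests of \eqn{(\hat\sigma^2_i / SE)^2}.  With
#' \code{lrt = TRUE} each component is additionally tested by a
#' likelihood-ratio test against the model without it, using the
#' boundary 50:50 mixture \eqn{\chi^2_0 : \chi^2_1} null.
#'
#' @param y numeric phenotype vector; rows with missing values are
#'   dropped (with a message), together with the matching rows of
#'   \code{X} and the matrices.
#' @param X covariate matrix (an intercept is added when absent);
#'   collinear columns are an error naming the columns.
#' @param matrices list of [RelationshipMatrix-class] objects (may be
#'   empty for the identity-only model).
#' @param constrainNonnegative constrain components to be non-negative.
#' @param tol log-likelihood convergence tolerance (1e-6).
#' @param maxit maximum iterations (100).
#' @param lrt also compute per-component likelihood-ratio tests.
#' @param verbose print the iteration trace.
#' @return a [VarianceFit-class].
#' @examples
#' ped <- simulatePedigree(150, 2, seed = 1)
#' mats <- buildEnvMatrices(ped)
#' ph <- simulatePhenotypes(ped, varC = 0.4, seed = 2)
#' remlFit(ph$pheno, matrices = list(mats$C))
#' @export
remlFit <- function(y, X = NULL, matrices = list(),
                    constrainNonnegative = TRUE, tol = 1e-6,
                    maxit = 100, lrt = FALSE, verbose = FALSE) {
  keep <- !is.na(y)
  if (any(!keep)) {
    message("dropping ", sum(!keep), " rows with missing phenotype")
    y <- y[keep]
    if (!is.null(X)) X <- X[keep, , drop = FALSE]
    matrices <- lapply(matrices, function(a) {
      a@values <- a@values[keep, keep, drop = FALSE]; a
    })
  }
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (qr(X)$rank < ncol(X)) {
    qrX <- qr(X)
    bad <- colnames(X)[-qrX$pivot[seq_len(qrX$rank)]]
    stop("collinear covariates: ", paste(bad, collapse = ", "))
  }
  labels <- vapply(matrices, component, character(1))
  A <- lapply(matrices, relValues)
  for (a in A) if (nrow(a) != n)
    stop("relationship matrix dimension does not match phenotype length")
  q <- length(A)
  p <- ncol(X)
  vp0 <- var(y)

  if (q == 0) {  # identity-only closed form
    b <- qr.coef(qr(X), y)
    rss <- sum((y - X %*% b)^2)
    s2 <- rss / (n - p)
    ll <- -0.5 * ((n - p) * log(s2) +
                    determinant(crossprod(X))$modulus[1] + (n - p))
    se <- s2 * sqrt(2 / (n - p))
    return(new("VarianceFit",
               estimates = c(E = 1), se = c(E = 0),
               varcomps = c(E = s2), varcompSE = c(E = se),
               loglik = as.numeric(ll), waldP = setNames(numeric(0), NULL),
               lrtP = setNames(numeric(0), NULL), converged = TRUE,
               constrained = constrainNonnegative, n = as.integer(n),
               vp = s2))
  }

  # V and its inverse live in buffers reused across iterations; the
  # C++ kernels fill them in place so each evaluation allocates only
  # n x p intermediates
  Vbuf <- matrix(0, n, n)
  Vibuf <- matrix(0, n, n)
  evalPoint <- function(sigma) {
    .fvBuildV(Vbuf, A, sigma, 0)
    logdetV <- .fvCholInv(Vbuf, Vibuf)
    if (is.na(logdetV)) {
      .fvBuildV(Vbuf, A, sigma, 1e-6 * vp0)
      logdetV <- .fvCholInv(Vbuf, Vibuf)
      if (is.na(logdetV))
        stop("total covariance matrix is not positive definite ",
             "even after bending")
    }
    Vi <- Vibuf
    ViX <- Vi %*% X
    XtViX <- crossprod(X, ViX)
    chX <- tryCatch(chol(XtViX), error = function(e)
      stop("collinear covariates in the GLS projection"))
    XtViXi <- chol2inv(chX)
    Py <- drop(Vi %*% y - ViX %*% (XtViXi %*% crossprod(ViX, y)))
    ll <- -0.5 * (logdetV + 2 * sum(log(diag(chX))) + sum(y * Py))
    APy <- vector("list", q + 1)
    trPA <- numeric(q + 1)
    for (i in seq_len(q)) {
      APy[[i]] <- drop(A[[i]] %*% Py)
      trPA[i] <- .fvTraceProd(Vi, A[[i]]) -
        sum(XtViXi * crossprod(ViX, A[[i]] %*% ViX))
    }
    APy[[q + 1]] <- Py
    trPA[q + 1] <- sum(diag(Vi)) - sum(XtViXi * crossprod(ViX))
    yPAPy <- vapply(APy, function(v) sum(Py * v), numeric(1))
    grad <- -0.5 * (trPA - yPAPy)
    AP <- do.call(cbind, APy)
    PAP <- Vi %*% AP - ViX %*% (XtViXi %*% crossprod(ViX, AP))
    AI <- 0.5 * crossprod(AP, PAP)
    list(ll = ll, grad = grad, AI = AI, yPAPy = yPAPy, trPA = trPA)
  }

  lo <- 1e-8 * vp0
  sigma <- rep(vp0 / (q + 1), q + 1)
  pinned <- rep(FALSE, q + 1)
  llPrev <- -Inf
  converged <- FALSE
  useEM <- TRUE  # first step is EM
  sigmaPrev <- sigma
  st <- evalPoint(sigma)
  for (it in seq_len(maxit)) {
    if (verbose)
      message(sprintf("it %2d  ll %.6f  sigma: %s", it, st$ll,
                      paste(signif(sigma, 4), collapse = " ")))
    if (it > 1 && abs(st$ll - llPrev) < tol) { converged <- TRUE; break }
    if (it > 1 && st$ll < llPrev - 1e-10 && !useEM) {
      # AI step overshot: back to previous point, take an EM step
      sigma <- sigmaPrev
      st <- evalPoint(sigma)
      useEM <- TRUE
    }
    llPrev <- st$ll
    sigmaPrev <- sigma
    if (useEM) {
      delta <- sigma^2 * (st$yPAPy - st$trPA) / n
      useEM <- FALSE
    } else {
      delta <- tryCatch(solve(st$AI, st$grad), error = function(e) NULL)
      if (is.null(delta))
        delta <- solve(st$AI + diag(1e-8 * max(diag(st$AI)), q + 1),
                       st$grad)
    }
    # apply the step with halving if it leaves the PD region
    for (half in 0:30) {
      cand <- sigma + delta / 2^half
      if (constrainNonnegative) {
        pinned <- cand < lo
        cand[pinned] <- lo
      } else if (cand[q + 1] < lo) {
        cand[q + 1] <- lo  # residual variance stays positive
      }
      stNew <- tryCatch(evalPoint(cand), error = function(e) NULL)
      if (!is.null(stNew)) break
    }
    if (is.null(stNew))
      stop("total covariance matrix is not positive definite ",
           "even after bending")
    sigma <- cand
    st <- stNew
  }

  if (constrainNonnegative && !converged && any(pinned)) {
    fit <- remlFit(y, X, matrices, constrainNonnegative = FALSE,
                   tol = tol, maxit = maxit, lrt = lrt,
                   verbose = verbose)
    fit@constrained <- FALSE
    return(fit)
  }

  covS <- tryCatch(solve(st$AI), error = function(e)
    solve(st$AI + diag(1e-8 * max(diag(st$AI)), q + 1)))
  seS <- sqrt(pmax(diag(covS), 0))
  tot <- sum(sigma)
  frac <- sigma / tot
  J <- (diag(q + 1) * tot - matrix(sigma, q + 1, q + 1)) / tot^2
  seF <- sqrt(pmax(diag(J %*% covS %*% t(J)), 0))
  nm <- c(labels, "E")
  wald <- setNames(pchisq((sigma[seq_len(q)] / seS[seq_len(q)])^2, 1,
                          lower.tail = FALSE), labels)
  lrtP <- setNames(rep(NA_real_, q), labels)
  fit <- new("VarianceFit",
             estimates = setNames(frac, nm), se = setNames(seF, nm),
             varcomps = setNames(sigma, nm),
             varcompSE = setNames(seS, nm),
             loglik = st$ll, waldP = wald, lrtP = lrtP,
             converged = converged, constrained = constrainNonnegative,
             n = as.integer(n), vp = tot)
  if (lrt && q > 0) {
    for (i in seq_len(q)) {
      red <- remlFit(y, X, matrices[-i],
                     constrainNonnegative = constrainNonnegative,
                     tol = tol, maxit = maxit, lrt = FALSE)
      fit@lrtP[labels[i]] <- lrtVariance(fit, red)$p
    }
  }
  fit
}

#' Likelihood-ratio test for one variance component on the boundary
#'
#' Tests a reduced model (one component removed) against the full
#' model.  The statistic \eqn{2\,\Delta\ell} is referred to the 50:50
#' mixture \eqn{\tfrac12\chi^2_0 + \tfrac12\chi^2_1}, the null for a
#' single variance component pinned at the zero boundary; a statistic
#' of 0 therefore reports p = 0.5 (the mixture mass at the boundary).
#'
#' @param full,reduced [VarianceFit-class] objects; \code{reduced} must
#'   be nested in \code{full} (its components a subset).
#' @return list with \code{statistic} and \code{p}.
#' @examples
#' # statistic 3.84 under the boundary mixture:
#' 0.5 * pchisq(3.84, 1, lower.tail = FALSE)  # 0.025
#' @export
lrtVariance <- function(full, reduced) {
  cf <- setdiff(names(full@estimates), "E")
  cr <- setdiff(names(reduced@estimates), "E")
  if (!all(cr %in% cf) || length(cr) >= length(cf) + 1)
    stop("models are not nested")
  stat <- max(0, 2 * (full@loglik - reduced@loglik))
  list(statistic = stat, p = 0.5 * pchisq(stat, 1, lower.tail = FALSE))
}
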