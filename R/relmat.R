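#' Genomic relationship matrix
#'
#' GCTA-style GRM:
#' \deqn{A_{jk} = \frac{1}{m_{jk}} \sum_i
#'   \frac{(x_{ij} - 2 p_i)(x_{ik} - 2 p_i)}{2 p_i (1 - p_i)}}
#' with \eqn{p_i} the sample allele frequency.  Missing genotypes are
#' mean-imputed per SNP (contributing zero after centring) and the
#' per-pair denominator \eqn{m_{jk}} counts only SNPs observed in both
#' individuals.
#'
#' @param geno a [GenotypeMatrix-class]; monomorphic SNPs are an error.
#' @param snps optional SNP IDs (or logical/integer index) restricting
#'   the matrix to a subset, e.g. all-but-one-chromosome.
#' @return a [RelationshipMatrix-class] with component \code{"G"}.
#' @examples
#' ped <- simulatePedigree(0, 0, nSingletons = 20, seed = 1)
#' gm <- simulateGenotypes(ped, 100, seed = 2)
#' grm <- buildGRM(gm)
#' mean(diag(relValues(grm)))  # ~ 1
#' @export
buildGRM <- function(geno, snps = NULL) {
  g <- geno@genotypes
  if (!is.null(snps)) g <- g[, snps, drop = FALSE]
  m <- ncol(g)
  p <- colMeans(g, na.rm = TRUE) / 2
  mono <- p <= 0 | p >= 1
  if (any(mono))
    stop("monomorphic SNP(s): ",
         paste(head(colnames(g)[mono], 5), collapse = ", "))
  hasNA <- anyNA(g)
  denom <- if (hasNA) {
    obs <- !is.na(g)
    storage.mode(obs) <- "double"
    tcrossprod(obs)
  } else m
  W <- g + 0  # force a copy; the kernel standardises it in place
  .fvStandardiseGeno(W, p)
  A <- tcrossprod(W) / denom
  dimnames(A) <- list(rownames(g), rownames(g))
  new("RelationshipMatrix", component = "G", values = A)
}

#' Pedigree numerator relationship matrix
#'
#' Expected additive relationship (twice the kinship coefficient) from
#' the pedigree, computed by the recursive tabular method: founders are
#' unrelated and non-inbred; for individual i with parents f and m,
#' \eqn{A_{ii} = 1 + A_{fm}/2} and \eqn{A_{ij} = (A_{fj} + A_{mj})/2}.
#' Children listed before parents are reordered internally; a cycle is
#' an error.
#'
#' @param ped a [Pedigree-class].
#' @return a [RelationshipMatrix-class] with component \code{"K"}.
#' @examples
#' ped <- simulatePedigree(1, 2, seed = 1)
#' relValues(buildPedigreeMatrix(ped))  # sibs and parent-offspring: 0.5
#' @export
buildPedigreeMatrix <- function(ped) {
  p <- ped@ped
  ord <- sortPedigreeOrder(p)
  ps <- p[ord, ]
  fa <- match(ps$pat, ps$iid, nomatch = 0L)
  mo <- match(ps$mat, ps$iid, nomatch = 0L)
  A <- .nrmTabular(fa, mo)
  dimnames(A) <- list(ps$iid, ps$iid)
  A <- A[match(p$iid, ps$iid), match(p$iid, ps$iid)]
  new("RelationshipMatrix", component = "K", values = A)
}

#' Shared-environment indicator matrices
#'
#' Builds the three \{0,1\} covariance structures of the family
#' environment model: \code{C} (1 iff spouses), \code{S} (1 iff full
#' siblings) and \code{F} (1 iff members of the same nuclear family,
#' i.e. a couple and their children).  All diagonals are 1, so the
#' couple and sibling supports are subsets of the family support.
#'
#' @param ped a [Pedigree-class]; an individual appearing in two
#'   couples is an error.
#' @param components which of \code{"F"}, \code{"C"}, \code{"S"} to
#'   build (all three by default).
#' @return named list of [RelationshipMatrix-class] objects
#'   \code{F}, \code{C}, \code{S} (the requested subset).
#' @export
buildEnvMatrices <- function(ped, components = c("F", "C", "S")) {
  p <- ped@ped
  n <- nrow(p)
  cpl <- p$couple[p$couple != "0"]
  if (length(cpl) && any(table(cpl) > 2))
    stop("a couple ID is shared by more than two individuals")
  if (anyDuplicated(p$iid))
    stop("individual present more than once (two couples?)")

  blockMatrix <- function(group, label) {
    M <- diag(1, n)
    dimnames(M) <- list(p$iid, p$iid)
    for (ix in split(seq_len(n), group)) {
      if (length(ix) > 1) M[ix, ix] <- 1
    }
    new("RelationshipMatrix", component = label, values = M)
  }
  # unique singleton groups so only true sharing sets form blocks
  cgrp <- ifelse(p$couple == "0", paste0(".c", seq_len(n)), p$couple)
  sgrp <- ifelse(p$pat == "0", paste0(".s", seq_len(n)),
                 paste(p$fid, p$pat, p$mat))
  out <- list()
  if ("F" %in% components) out$F <- blockMatrix(p$fid, "F")
  if ("C" %in% components) out$C <- blockMatrix(cgrp, "C")
  if ("S" %in% components) out$S <- blockMatrix(sgrp, "S")
  out
}

#' Diagonal bending for singular covariance structures
#'
#' Adds \code{eps} to the diagonal so that a positive semi-definite but
#' singular structure (an indicator matrix, or a GRM with more
#' individuals than SNPs) admits a Cholesky factorisation inside the
#' REML solver.
#'
#' @param rm a [RelationshipMatrix-class] or plain matrix.
#' @param eps ridge added to the diagonal (default 1e-6).
#' @return object of the same kind with the bent values.
#' @export
bendMatrix <- function(rm, eps = 1e-6) {
  if (is(rm, "RelationshipMatrix")) {
    rm@values <- rm@values + diag(eps, nrow(rm@values))
    rm
  } else {
    rm + diag(eps, nrow(rm))
  }
}

#' Leading principal components of a genomic relationship matrix
#'
#' Eigenvectors of the GRM scaled by the square root of their
#' eigenvalues, used as fixed-effect covariates controlling for
#' population structure.
#'
#' @param grm a [RelationshipMatrix-class] (component \code{"G"}).
#' @param nPCs number of components.
#' @return matrix of \code{nPCs} columns, rownames = individual IDs.
#' @export
grmPrincipalComponents <- function(grm, nPCs = 20) {
  e <- eigen(relValues(grm), symmetric = TRUE)
  k <- min(nPCs, ncol(e$vectors))
  pcs <- e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pmax(e$values[seq_len(k)], 0)), k)
  rownames(pcs) <- sampleIds(grm)
  colnames(pcs) <- paste0("PC", seq_len(k))
  pcs
}
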