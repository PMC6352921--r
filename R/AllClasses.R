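#' @useDynLib famvar, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats var sd cor dnorm qnorm pnorm rnorm runif rbinom
#'   pchisq qchisq pf optimize setNames complete.cases p.adjust
#'   na.omit quantile median rpois aggregate lm resid coef
#' @importFrom utils read.table write.table head
NULL

#' Pedigree of a family cohort
#'
#' Holds one row per individual with family ID, parental IDs (\code{"0"}
#' for founders), sex and a couple ID linking spouse pairs.  Couples are
#' founders; each nuclear family is a couple plus their children, and
#' singletons form their own single-member family.
#'
#' @slot ped \code{data.frame} with columns \code{fid}, \code{iid},
#'   \code{pat}, \code{mat}, \code{sex} (1 = male, 2 = female) and
#'   \code{couple} (\code{"0"} for individuals not in a couple).
#'
#' @seealso [simulatePedigree()], [buildPedigreeMatrix()],
#'   [buildEnvMatrices()]
#' @export
setClass("Pedigree", representation(ped = "data.frame"))

setValidity("Pedigree", function(object) {
  p <- object@ped
  need <- c("fid", "iid", "pat", "mat", "sex", "couple")
  if (!all(need %in% names(p)))
    return(paste("pedigree must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(p$iid)) return("individual IDs must be unique")
  known <- c("0", p$iid)
  if (!all(p$pat %in% known) || !all(p$mat %in% known))
    return("parent IDs must be 0 or refer to individuals in the pedigree")
  both <- (p$pat == "0") == (p$mat == "0")
  if (!all(both)) return("each individual has either two parents or none")
  TRUE
})

#' Genotype matrix with SNP map
#'
#' Biallelic genotypes coded as dosage of the A1 (effect) allele in
#' \{0, 1, 2\}, \code{NA} for missing, individuals in rows and SNPs in
#' columns, alongside a PLINK-style map (chromosome, 1-based base-pair
#' position, A1/A2 alleles).
#'
#' @slot genotypes numeric matrix, individuals x SNPs, rownames =
#'   individual IDs, colnames = SNP IDs.
#' @slot map \code{data.frame} with columns \code{snp}, \code{chr},
#'   \code{bp}, \code{a1}, \code{a2}.
#'
#' @seealso [simulateGenotypes()], [qcGenotypes()], [buildGRM()]
#' @export
setClass("GenotypeMatrix",
         representation(genotypes = "matrix", map = "data.frame"))

setValidity("GenotypeMatrix", function(object) {
  g <- object@genotypes
  m <- object@map
  if (ncol(g) != nrow(m)) return("map rows must match genotype columns")
  need <- c("snp", "chr", "bp", "a1", "a2")
  if (!all(need %in% names(m)))
    return(paste("map must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(m$snp)) return("SNP IDs must be unique")
  rng <- range(g, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) return("genotypes must lie in [0, 2]")
  ok <- tapply(m$bp, m$chr, function(x) all(diff(x) > 0))
  if (!all(ok)) return("bp positions must be strictly increasing per chromosome")
  TRUE
})

#' Relationship (covariance-structure) matrix
#'
#' A symmetric N x N covariance structure labelled by the variance
#' component it models: \code{"G"} (genomic relationship matrix),
#' \code{"K"} (pedigree numerator relationship), or the \{0,1\}
#' indicator structures \code{"F"} (nuclear family), \code{"C"}
#' (couple) and \code{"S"} (full siblings).
#'
#' @slot component single character label.
#' @slot values symmetric numeric matrix with dimnames = individual IDs.
#'
#' @seealso [buildGRM()], [buildPedigreeMatrix()], [buildEnvMatrices()],
#'   [remlFit()]
#' @export
setClass("RelationshipMatrix",
         representation(component = "character", values = "matrix"))

setValidity("RelationshipMatrix", function(object) {
  v <- object@values
  n <- nrow(v)
  if (n != ncol(v)) return("matrix must be square")
  if (is.null(rownames(v))) return("matrix must carry individual IDs as dimnames")
  # full symmetry check up to moderate size, sampled beyond (avoids an
  # n x n transpose copy on cohort-scale matrices)
  sym <- if (n <= 1500) {
    isTRUE(all.equal(v, t(v), tolerance = 1e-10,
                     check.attributes = FALSE))
  } else {
    i <- sample.int(n, 2000, replace = TRUE)
    j <- sample.int(n, 2000, replace = TRUE)
    max(abs(v[cbind(i, j)] - v[cbind(j, i)])) < 1e-8
  }
  if (!sym) return("matrix must be symmetric")
  if (length(object@component) != 1L) return("component must be a single label")
  TRUE
})

#' REML variance-component fit
#'
#' Result of fitting the linear mixed model
#' \eqn{y = Xb + \sum_i u_i + e}, \eqn{u_i \sim N(0, \sigma^2_i A_i)},
#' by restricted maximum likelihood.  Components are reported as
#' fractions of the total phenotypic variance (the parameterisation used
#' when summarising family cohorts); absolute variances are kept too.
#'
#' @slot estimates named fractions of phenotypic variance, one per
#'   component plus \code{"E"} (residual).
#' @slot se delta-method standard errors of those fractions.
#' @slot varcomps,varcompSE absolute variance components and their SEs.
#' @slot loglik REML log-likelihood.
#' @slot waldP two-sided Wald \eqn{\chi^2_1} p-value per non-residual
#'   component.
#' @slot lrtP boundary-mixture likelihood-ratio p-value per component
#'   (\code{NA} until computed, see [remlFit()] argument \code{lrt}).
#' @slot converged,constrained logical flags; \code{constrained = FALSE}
#'   marks an unconstrained refit performed after a pinned constrained
#'   fit failed to converge.
#' @slot n number of individuals used.
#' @slot vp total phenotypic variance (sum of all components).
#' @export
setClass("VarianceFit",
         representation(estimates = "numeric", se = "numeric",
                        varcomps = "numeric", varcompSE = "numeric",
                        loglik = "numeric", waldP = "numeric",
                        lrtP = "numeric", converged = "logical",
                        constrained = "logical", n = "integer",
                        vp = "numeric"))

#' Polygenic risk score profile
#'
#' Per-individual scores across a grid of p-value inclusion thresholds;
#' the score at threshold t is the cumulative weighted allele count over
#' all retained SNPs with discovery p <= t.
#'
#' @slot scores numeric matrix, individuals x thresholds.
#' @slot thresholds increasing p-value grid.
#' @slot nSnps number of SNPs contributing at each threshold.
#' @slot bestThreshold,bestR2 filled by [bestThreshold()] (NA before).
#' @export
setClass("PRSProfile",
         representation(scores = "matrix", thresholds = "numeric",
                        nSnps = "integer", bestThreshold = "numeric",
                        bestR2 = "numeric"))

setValidity("PRSProfile", function(object) {
  if (length(object@thresholds) != ncol(object@scores))
    return("one score column per threshold required")
  if (is.unsorted(object@thresholds, strictly = TRUE))
    return("thresholds must be strictly increasing")
  TRUE
})
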