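#' @rdname Pedigree-class
#' @param object,x a \code{Pedigree}, \code{GenotypeMatrix} or
#'   \code{RelationshipMatrix}
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("snpMap", function(x) standardGeneric("snpMap"))

#' @rdname RelationshipMatrix-class
#' @export
setGeneric("component", function(x) standardGeneric("component"))

#' @rdname RelationshipMatrix-class
#' @export
setGeneric("relValues", function(x) standardGeneric("relValues"))

#' @rdname RelationshipMatrix-class
#' @export
setGeneric("nNonzeroOffdiag", function(x) standardGeneric("nNonzeroOffdiag"))

#' @rdname Pedigree-class
#' @export
setGeneric("pedTable", function(x) standardGeneric("pedTable"))

#' @rdname VarianceFit-class
#' @param x a \code{VarianceFit}
#' @export
setGeneric("estimates", function(x) standardGeneric("estimates"))

#' @rdname VarianceFit-class
#' @export
setGeneric("stdErrors", function(x) standardGeneric("stdErrors"))

setMethod("sampleIds", "Pedigree", function(x) x@ped$iid)
setMethod("sampleIds", "GenotypeMatrix", function(x) rownames(x@genotypes))
setMethod("sampleIds", "RelationshipMatrix", function(x) rownames(x@values))
setMethod("pedTable", "Pedigree", function(x) x@ped)
setMethod("genotypes", "GenotypeMatrix", function(x) x@genotypes)
setMethod("snpMap", "GenotypeMatrix", function(x) x@map)
setMethod("component", "RelationshipMatrix", function(x) x@component)
setMethod("relValues", "RelationshipMatrix", function(x) x@values)
setMethod("nNonzeroOffdiag", "RelationshipMatrix", function(x) {
  v <- x@values
  sum(v[upper.tri(v)] != 0) * 2L
})
setMethod("estimates", "VarianceFit", function(x) x@estimates)
setMethod("stdErrors", "VarianceFit", function(x) x@se)

setMethod("show", "Pedigree", function(object) {
  p <- object@ped
  cnt <- pedigreeCounts(object)
  cat("Pedigree with", nrow(p), "individuals in",
      length(unique(p$fid)), "families\n")
  cat("  couples:", cnt$nCouples, " full-sib pairs:", cnt$nSibPairs,
      " nuclear families (>=2):", cnt$nNuclearFamilies, "\n")
})

setMethod("show", "GenotypeMatrix", function(object) {
  g <- object@genotypes
  cat("GenotypeMatrix:", nrow(g), "individuals x", ncol(g), "SNPs on",
      length(unique(object@map$chr)), "chromosome(s)\n")
  nm <- sum(is.na(g))
  if (nm > 0) cat("  missing genotypes:", nm, "\n")
})

setMethod("show", "RelationshipMatrix", function(object) {
  v <- object@values
  cat("RelationshipMatrix [", object@component, "]: ", nrow(v), " x ",
      ncol(v), ", ", nNonzeroOffdiag(object),
      " non-zero off-diagonal entries\n", sep = "")
})

setMethod("show", "VarianceFit", function(object) {
  cat("VarianceFit (REML", if (!object@constrained) ", unconstrained" else "",
      if (!object@converged) ", NOT converged" else "", ")\n", sep = "")
  est <- object@estimates
  tab <- data.frame(fraction = round(est, 4),
                    se = round(object@se, 4))
  wp <- object@waldP[names(est)]
  lp <- object@lrtP[names(est)]
  tab$waldP <- signif(wp, 3)
  tab$lrtP <- signif(lp, 3)
  print(tab)
  cat("logLik:", format(object@loglik), "  n:", object@n,
      "  Vp:", round(object@vp, 4), "\n")
})

setMethod("show", "PRSProfile", function(object) {
  cat("PRSProfile:", nrow(object@scores), "individuals x",
      length(object@thresholds), "thresholds (p <=",
      min(object@thresholds), "...", max(object@thresholds), ")\n")
  if (!is.na(object@bestThreshold))
    cat("  best threshold:", object@bestThreshold,
        " incremental r2:", signif(object@bestR2, 4), "\n")
})
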