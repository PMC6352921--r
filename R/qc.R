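#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test: the p-value is the total probability, under
#' the hypergeometric distribution of heterozygote counts conditional
#' on allele counts, of all genotype configurations no more probable
#' than the observed one.
#'
#' @param nAA,nAa,naa genotype counts (major hom, het, minor hom).
#' @return exact p-value.
#' @export
hweExactP <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  if (n == 0) return(1)
  rare <- 2 * min(nAA, naa) + nAa
  if (rare == 0) return(1)
  # possible heterozygote counts share the parity of the rare-allele count
  hets <- seq(rare %% 2, min(rare, 2 * n - rare), by = 2)
  # unnormalised probabilities via the standard multiplicative recurrence,
  # anchored at the largest het count for numerical stability
  lp <- numeric(length(hets))
  for (i in seq_along(hets)[-1]) {
    h <- hets[i]
    # P(h) / P(h-2) = 4 * nr(h-2) * nc(h-2) / (h * (h-1))
    nr <- (rare - hets[i - 1]) / 2       # rare homs at previous het count
    nc <- n - hets[i - 1] - nr           # common homs at previous
    lp[i] <- lp[i - 1] + log(4 * nr * nc) - log(h * (h - 1))
  }
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- pr[match(nAa, hets)]
  sum(pr[pr <= obs + 1e-12])
}

#' Genotype quality control
#'
#' Applies the standard GWAS filters in order: individuals with a
#' missing rate above \code{indivMissingMax}, then SNPs with call rate
#' below \code{callrateMin}, minor allele frequency below \code{mafMin},
#' and exact-test Hardy-Weinberg p-value at or below \code{hwePMin}
#' (founders only, to avoid counting transmitted alleles twice when a
#' pedigree is supplied).
#'
#' @param geno a [GenotypeMatrix-class] (values 0/1/2/NA).
#' @param callrateMin minimum SNP call rate (default 0.98).
#' @param indivMissingMax maximum per-individual missing rate (0.02).
#' @param mafMin minimum minor allele frequency (0.01).
#' @param hwePMin HWE exact-test p threshold (1e-6); SNPs with
#'   \code{p <= hwePMin} are removed.
#' @param ped optional [Pedigree-class] to restrict the HWE test to
#'   founders.
#' @return list with the filtered \code{genotypes}
#'   ([GenotypeMatrix-class]) and a \code{report} list of removal
#'   counts.
#' @export
qcGenotypes <- function(geno, callrateMin = 0.98, indivMissingMax = 0.02,
                        mafMin = 0.01, hwePMin = 1e-6, ped = NULL) {
  g <- geno@genotypes
  map <- geno@map
  rep0 <- list()

  # individuals with missing rate at or above the maximum are removed
  indMiss <- rowMeans(is.na(g))
  keepInd <- indMiss < indivMissingMax
  rep0$individualsRemovedMissing <- sum(!keepInd)
  g <- g[keepInd, , drop = FALSE]

  call <- colMeans(!is.na(g))
  keepCall <- call >= callrateMin
  rep0$snpsRemovedCallrate <- sum(!keepCall)
  g <- g[, keepCall, drop = FALSE]
  map <- map[keepCall, , drop = FALSE]

  p <- colMeans(g, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keepMaf <- maf >= mafMin
  rep0$snpsRemovedMaf <- sum(!keepMaf)
  g <- g[, keepMaf, drop = FALSE]
  map <- map[keepMaf, , drop = FALSE]

  gh <- g
  if (!is.null(ped)) {
    pd <- ped@ped
    fnd <- pd$iid[pd$pat == "0"]
    gh <- g[rownames(g) %in% fnd, , drop = FALSE]
  }
  hwe <- vapply(seq_len(ncol(gh)), function(j) {
    x <- gh[, j]
    hweExactP(sum(x == 0, na.rm = TRUE), sum(x == 1, na.rm = TRUE),
              sum(x == 2, na.rm = TRUE))
  }, numeric(1))
  keepHwe <- hwe > hwePMin
  rep0$snpsRemovedHwe <- sum(!keepHwe)
  g <- g[, keepHwe, drop = FALSE]
  map <- map[keepHwe, , drop = FALSE]

  rep0$snpsRemaining <- ncol(g)
  rep0$individualsRemaining <- nrow(g)
  if (ncol(g) == 0)
    stop("quality control removed every SNP; check thresholds")
  rownames(map) <- NULL
  list(genotypes = new("GenotypeMatrix", genotypes = g, map = map),
       report = rep0)
}
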