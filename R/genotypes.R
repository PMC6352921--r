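#' Simulate biallelic genotypes on a pedigree
#'
#' Founder haplotypes are drawn at Hardy-Weinberg equilibrium at
#' per-SNP minor allele frequencies sampled uniformly from
#' \code{mafRange}; optional linkage disequilibrium is induced within
#' consecutive blocks of \code{ldBlockSize} SNPs by an exchangeable
#' Gaussian-copula correlation \code{ldRho} among founder haplotypes.
#' Non-founders receive one allele from each parent, transmitted
#' haplotype-block-wise (blocks segregate independently, no
#' recombination within a block), so Mendelian constraints hold exactly
#' and within-block LD survives transmission.
#'
#' @param ped a [Pedigree-class]; children listed before parents are
#'   reordered internally.
#' @param nSnps total number of SNPs.
#' @param mafRange interval in (0, 0.5] for per-SNP allele frequencies.
#' @param nChromosomes number of chromosomes SNPs are spread over.
#' @param ldBlockSize SNPs per LD block (1 = linkage equilibrium).
#' @param ldRho within-block founder-haplotype correlation in [0, 1).
#' @param seed integer seed.
#' @return a [GenotypeMatrix-class] with A1 dosages in \{0, 1, 2\}.
#' @examples
#' ped <- simulatePedigree(10, 2, seed = 1)
#' gm <- simulateGenotypes(ped, nSnps = 50, seed = 2)
#' @export
simulateGenotypes <- function(ped, nSnps, mafRange = c(0.05, 0.5),
                              nChromosomes = 1, ldBlockSize = 1,
                              ldRho = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (mafRange[1] <= 0 || mafRange[2] > 0.5)
    stop("mafRange lower bound must be > 0 and upper bound <= 0.5")
  if (ldRho < 0 || ldRho >= 1) stop("ldRho must lie in [0, 1)")
  p <- ped@ped
  ord <- sortPedigreeOrder(p)
  sorted <- identical(ord, seq_len(nrow(p)))
  p <- p[ord, ]
  n <- nrow(p)

  # map: SNPs split evenly over chromosomes, random increasing positions
  chr <- rep(seq_len(nChromosomes), length.out = nSnps)
  chr <- sort(chr)
  bp <- unlist(lapply(split(seq_len(nSnps), chr), function(ix)
    cumsum(sample(1000:9999, length(ix), replace = TRUE))), use.names = FALSE)
  pairType <- sample(1:2, nSnps, replace = TRUE)
  map <- data.frame(snp = sprintf("snp%06d", seq_len(nSnps)),
                    chr = chr, bp = bp,
                    a1 = c("A", "C")[pairType],  # A/G or C/T pairs:
                    a2 = c("G", "T")[pairType],  # never strand-ambiguous
                    stringsAsFactors = FALSE)
  maf <- runif(nSnps, mafRange[1], mafRange[2])

  # block structure (blocks never span chromosomes)
  blk <- unlist(lapply(split(seq_len(nSnps), chr), function(ix)
    rep(seq_len(ceiling(length(ix) / ldBlockSize)),
        each = ldBlockSize)[seq_along(ix)]), use.names = FALSE)
  blk <- cumsum(c(1L, diff(blk) != 0 | diff(chr) != 0))
  nBlk <- max(blk)

  founder <- p$pat == "0"
  nF <- sum(founder)

  if (ldRho == 0 || ldBlockSize == 1) {
    # linkage equilibrium: Hardy-Weinberg founders and per-SNP
    # Mendelian transmission in compiled code
    fa <- match(p$pat, p$iid, nomatch = 0L)
    mo <- match(p$mat, p$iid, nomatch = 0L)
    G <- .fvSimGenoLE(nSnps, maf, fa, mo)
    dimnames(G) <- list(p$iid, map$snp)
    if (!sorted) G <- G[match(ped@ped$iid, p$iid), , drop = FALSE]
    return(new("GenotypeMatrix", genotypes = G, map = map))
  }

  thr <- qnorm(maf)

  drawHap <- function(nh) {
    # latent exchangeable-within-block Gaussian, thresholded at qnorm(maf)
    if (ldRho > 0) {
      u0 <- matrix(rnorm(nh * nBlk), nh, nBlk)[, blk, drop = FALSE]
      z <- sqrt(ldRho) * u0 +
        sqrt(1 - ldRho) * matrix(rnorm(nh * nSnps), nh, nSnps)
    } else {
      z <- matrix(rnorm(nh * nSnps), nh, nSnps)
    }
    matrix(as.integer(z < rep(thr, each = nh)), nh, nSnps)
  }

  H1 <- matrix(0L, n, nSnps)
  H2 <- matrix(0L, n, nSnps)
  H1[founder, ] <- drawHap(nF)
  H2[founder, ] <- drawHap(nF)

  done <- founder
  while (!all(done)) {
    fa <- match(p$pat, p$iid)
    mo <- match(p$mat, p$iid)
    wave <- which(!done & done[fa] & done[mo])
    if (!length(wave)) stop("pedigree contains a cycle")
    nw <- length(wave)
    pick <- function(Ha, Hb, par) {
      B <- matrix(runif(nw * nBlk) < 0.5, nw, nBlk)[, blk, drop = FALSE]
      B * Ha[par, , drop = FALSE] + (1 - B) * Hb[par, , drop = FALSE]
    }
    H1[wave, ] <- pick(H1, H2, fa[wave])
    H2[wave, ] <- pick(H1, H2, mo[wave])
    done[wave] <- TRUE
  }

  G <- H1 + H2
  storage.mode(G) <- "double"
  dimnames(G) <- list(p$iid, map$snp)
  # restore original pedigree order
  if (!sorted) G <- G[match(ped@ped$iid, p$iid), , drop = FALSE]
  new("GenotypeMatrix", genotypes = G, map = map)
}
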