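#' Write genotypes and pedigree as PLINK bed/bim/fam
#'
#' Writes the binary v1.9 dialect: magic bytes \code{6c 1b 01}
#' (SNP-major), two bits per genotype (\code{00} = homozygous A1,
#' \code{10} = heterozygous, \code{11} = homozygous A2, \code{01} =
#' missing), \code{.bim} with 1-based positions and \code{.fam} with
#' family/parent IDs.  The couple column, which PLINK's fam format
#' lacks, is written by [writePedigreeTable()].
#'
#' @param geno [GenotypeMatrix-class] (A1-dosage coding).
#' @param ped [Pedigree-class] covering the genotyped individuals.
#' @param prefix output path prefix.
#' @return \code{prefix}, invisibly.
#' @export
writePlink <- function(geno, ped, prefix) {
  g <- geno@genotypes
  map <- geno@map
  p <- ped@ped[match(rownames(g), ped@ped$iid), ]
  write.table(data.frame(p$fid, p$iid, p$pat, p$mat, p$sex, -9),
              paste0(prefix, ".fam"), quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  write.table(data.frame(map$chr, map$snp, 0, map$bp, map$a1, map$a2),
              paste0(prefix, ".bim"), quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  n <- nrow(g)
  codes <- c(`0` = 3L, `1` = 2L, `2` = 0L)  # dosage of A1 -> 2-bit code
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  nBytes <- ceiling(n / 4)
  pad <- nBytes * 4
  for (j in seq_len(ncol(g))) {
    x <- g[, j]
    cd <- rep(1L, pad)  # 01 = missing
    ok <- !is.na(x)
    cd[seq_len(n)][ok] <- codes[as.character(x[ok])]
    cd[seq_len(pad) > n] <- 0L
    m4 <- matrix(cd, 4, nBytes)
    bytes <- m4[1, ] + m4[2, ] * 4L + m4[3, ] * 16L + m4[4, ] * 64L
    writeBin(as.raw(bytes), con)
  }
  invisible(prefix)
}

#' Read PLINK bed/bim/fam
#'
#' Parses the v1.9 SNP-major binary dialect back into a genotype
#' matrix (A1-dosage coding, honouring the .bim A1 = effect allele
#' convention) and a pedigree.  A wrong magic byte or a truncated .bed
#' is an explicit error.
#'
#' @param prefix path prefix of the three files.
#' @return list with \code{genotypes} ([GenotypeMatrix-class]) and
#'   \code{pedigree} ([Pedigree-class], couple IDs \code{"0"}).
#' @export
readPlink <- function(prefix) {
  fam <- read.table(paste0(prefix, ".fam"), stringsAsFactors = FALSE,
                    col.names = c("fid", "iid", "pat", "mat", "sex",
                                  "pheno"), colClasses = "character")
  bim <- read.table(paste0(prefix, ".bim"), stringsAsFactors = FALSE,
                    col.names = c("chr", "snp", "cm", "bp", "a1", "a2"))
  n <- nrow(fam); m <- nrow(bim)
  raw <- readBin(paste0(prefix, ".bed"), "raw",
                 n = 3 + ceiling(n / 4) * m)
  if (length(raw) < 3 || raw[1] != 0x6c || raw[2] != 0x1b)
    stop("not a PLINK .bed file (magic bytes mismatch)")
  if (raw[3] != 0x01)
    stop("only the SNP-major .bed layout is supported")
  nBytes <- ceiling(n / 4)
  if (length(raw) != 3 + nBytes * m)
    stop("truncated .bed: expected ", 3 + nBytes * m, " bytes, got ",
         length(raw))
  body <- as.integer(raw[-(1:3)])
  # unpack 2-bit codes: 4 individuals per byte, low bits first
  lut <- cbind(0:255 %% 4L, (0:255 %/% 4L) %% 4L,
               (0:255 %/% 16L) %% 4L, 0:255 %/% 64L)
  codes <- matrix(as.vector(t(lut[body + 1L, , drop = FALSE])),
                  4L * nBytes, m)[seq_len(n), , drop = FALSE]
  deco <- c(2, NA, 1, 0)  # code 0,1,2,3 -> A1 dosage
  g <- matrix(deco[codes + 1L], n, m,
              dimnames = list(fam$iid, bim$snp))
  map <- data.frame(snp = bim$snp, chr = as.integer(bim$chr),
                    bp = as.integer(bim$bp), a1 = bim$a1, a2 = bim$a2,
                    stringsAsFactors = FALSE)
  ped <- data.frame(fid = fam$fid, iid = fam$iid, pat = fam$pat,
                    mat = fam$mat, sex = as.integer(fam$sex),
                    couple = "0", stringsAsFactors = FALSE)
  list(genotypes = new("GenotypeMatrix", genotypes = g, map = map),
       pedigree = new("Pedigree", ped = ped))
}

#' Write / read a pedigree table with couple IDs
#'
#' Tab-separated with header FID IID PAT MAT SEX COUPLE_ID.
#'
#' @param ped a [Pedigree-class].
#' @param path file path.
#' @return \code{path} invisibly / a [Pedigree-class].
#' @export
writePedigreeTable <- function(ped, path) {
  p <- ped@ped
  out <- data.frame(FID = p$fid, IID = p$iid, PAT = p$pat, MAT = p$mat,
                    SEX = p$sex, COUPLE_ID = p$couple)
  write.table(out, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' @rdname writePedigreeTable
#' @export
readPedigreeTable <- function(path) {
  d <- read.table(path, header = TRUE, stringsAsFactors = FALSE,
                  colClasses = "character")
  new("Pedigree",
      ped = data.frame(fid = d$FID, iid = d$IID, pat = d$PAT,
                       mat = d$MAT, sex = as.integer(d$SEX),
                       couple = d$COUPLE_ID, stringsAsFactors = FALSE))
}

#' Write / read a GRM in the GCTA binary dialect
#'
#' \code{.grm.bin} holds the lower triangle (including the diagonal)
#' row-wise as float32, \code{.grm.N.bin} the per-pair SNP counts and
#' \code{.grm.id} the family/individual IDs.
#'
#' @param rm a [RelationshipMatrix-class].
#' @param prefix output prefix.
#' @param nSnps SNP count recorded per pair (a single number is
#'   recycled).
#' @return \code{prefix} invisibly / a [RelationshipMatrix-class].
#' @export
writeGRMBin <- function(rm, prefix, nSnps = 1) {
  v <- relValues(rm)
  n <- nrow(v)
  # row-wise lower triangle including the diagonal
  tri <- unlist(lapply(seq_len(n), function(i) v[i, seq_len(i)]))
  con <- file(paste0(prefix, ".grm.bin"), "wb")
  writeBin(as.numeric(tri), con, size = 4)
  close(con)
  con <- file(paste0(prefix, ".grm.N.bin"), "wb")
  writeBin(as.numeric(rep(nSnps, length.out = length(tri))), con,
           size = 4)
  close(con)
  ids <- sampleIds(rm)
  write.table(data.frame(ids, ids), paste0(prefix, ".grm.id"),
              quote = FALSE, sep = "\t", row.names = FALSE,
              col.names = FALSE)
  invisible(prefix)
}

#' @rdname writeGRMBin
#' @param label component label to assign on read (default "G").
#' @export
readGRMBin <- function(prefix, label = "G") {
  ids <- read.table(paste0(prefix, ".grm.id"),
                    stringsAsFactors = FALSE)[, 2]
  n <- length(ids)
  nt <- n * (n + 1) / 2
  tri <- readBin(paste0(prefix, ".grm.bin"), "numeric", n = nt,
                 size = 4)
  if (length(tri) != nt) stop("truncated .grm.bin")
  v <- matrix(0, n, n, dimnames = list(ids, ids))
  k <- 1
  for (i in seq_len(n)) {
    v[i, seq_len(i)] <- tri[k:(k + i - 1)]
    k <- k + i
  }
  v[upper.tri(v)] <- t(v)[upper.tri(v)]
  new("RelationshipMatrix", component = label, values = v)
}

#' Write / read summary statistics TSV
#'
#' Columns SNP, CHR, BP, A1, A2, BETA (or OR), SE, P, N; an OR column
#' is log-transformed to BETA on read.
#'
#' @param stats summary-statistics \code{data.frame}.
#' @param path file path.
#' @return \code{path} invisibly / a \code{data.frame} with the
#'   package's lower-case column names.
#' @export
writeSumstats <- function(stats, path) {
  out <- data.frame(SNP = stats$snp, CHR = stats$chr, BP = stats$bp,
                    A1 = stats$a1, A2 = stats$a2, BETA = stats$beta,
                    SE = stats$se, P = stats$p, N = stats$n)
  write.table(out, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' @rdname writeSumstats
#' @export
readSumstats <- function(path) {
  d <- read.table(path, header = TRUE, stringsAsFactors = FALSE)
  names(d) <- toupper(names(d))
  beta <- if ("BETA" %in% names(d)) d$BETA else {
    if (!"OR" %in% names(d)) stop("need a BETA or OR column")
    log(d$OR)
  }
  data.frame(snp = d$SNP, chr = d$CHR, bp = d$BP, a1 = d$A1, a2 = d$A2,
             beta = beta, se = d$SE, p = d$P,
             n = if ("N" %in% names(d)) d$N else NA_integer_,
             stringsAsFactors = FALSE)
}

#' Write / read a phenotype table (FID, IID, trait columns)
#' @param pheno \code{data.frame} with \code{fid}, \code{iid} and trait
#'   columns.
#' @param path file path.
#' @return \code{path} invisibly / a \code{data.frame}.
#' @export
writePhenoTable <- function(pheno, path) {
  out <- pheno
  names(out)[match(c("fid", "iid"), names(out))] <- c("FID", "IID")
  write.table(out, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' @rdname writePhenoTable
#' @export
readPhenoTable <- function(path) {
  d <- read.table(path, header = TRUE, stringsAsFactors = FALSE)
  names(d)[match(c("FID", "IID"), names(d))] <- c("fid", "iid")
  d
}

#' Write / read a relationship matrix as a plain TSV
#'
#' Long format with one row per (i, j) pair of the lower triangle
#' including the diagonal: columns ID1, ID2, VALUE.
#'
#' @param rm a [RelationshipMatrix-class].
#' @param path file path.
#' @return \code{path} invisibly / a [RelationshipMatrix-class].
#' @export
writeGRMTable <- function(rm, path) {
  v <- relValues(rm)
  ids <- sampleIds(rm)
  ij <- which(lower.tri(v, diag = TRUE), arr.ind = TRUE)
  out <- data.frame(ID1 = ids[ij[, 1]], ID2 = ids[ij[, 2]],
                    VALUE = v[ij])
  write.table(out, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' @rdname writeGRMTable
#' @param label component label to assign on read (default "G").
#' @export
readGRMTable <- function(path, label = "G") {
  d <- read.table(path, header = TRUE, stringsAsFactors = FALSE,
                  colClasses = c("character", "character", "numeric"))
  ids <- unique(c(d$ID1, d$ID2))
  v <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  v[cbind(d$ID1, d$ID2)] <- d$VALUE
  v[cbind(d$ID2, d$ID1)] <- d$VALUE
  new("RelationshipMatrix", component = label, values = v)
}

#' Write / read LD scores as TSV (SNP, CHR, BP, L2)
#'
#' @param ld LD-score \code{data.frame} as from [ldScores()].
#' @param path file path.
#' @return \code{path} invisibly / a \code{data.frame} with the
#'   package's column names.
#' @export
writeLDScores <- function(ld, path) {
  out <- data.frame(SNP = ld$snp, CHR = ld$chr, BP = ld$bp,
                    L2 = ld$ldScore)
  write.table(out, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' @rdname writeLDScores
#' @export
readLDScores <- function(path) {
  d <- read.table(path, header = TRUE, stringsAsFactors = FALSE)
  data.frame(snp = d$SNP, chr = d$CHR, bp = d$BP, ldScore = d$L2,
             stringsAsFactors = FALSE)
}

#' Write a polygenic score profile as TSV
#'
#' One row per individual, one column per p-value threshold (plus the
#' individual ID).
#'
#' @param profile a [PRSProfile-class].
#' @param path file path.
#' @return \code{path} invisibly.
#' @export
writeProfileTable <- function(profile, path) {
  sc <- profile@scores
  out <- data.frame(IID = rownames(sc), sc, check.names = FALSE)
  names(out)[-1] <- paste0("P", profile@thresholds)
  write.table(out, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}
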