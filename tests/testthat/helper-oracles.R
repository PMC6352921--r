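# Independent oracles and fixture builders shared across the suite.
# Each oracle re-derives the quantity by a different route than the
# package implementation.

# kinship coefficient by the classic recursion phi(i, j); the package
# uses the tabular method, this walks the pedigree top-down instead
kinshipOracle <- function(ped) {
  p <- if (is(ped, "Pedigree")) pedTable(ped) else ped
  n <- nrow(p)
  fa <- match(p$pat, p$iid, nomatch = 0L)
  mo <- match(p$mat, p$iid, nomatch = 0L)
  memo <- new.env()
  phi <- function(i, j) {
    if (i == 0 || j == 0) return(0)
    key <- paste(min(i, j), max(i, j))
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (i == j) {
      0.5 * (1 + phi(fa[i], mo[i]))
    } else {
      # recurse on the younger individual (appears later in a
      # parents-first ordering)
      a <- max(i, j); b <- min(i, j)
      0.5 * (phi(fa[a], b) + phi(mo[a], b))
    }
    memo[[key]] <- val
    val
  }
  A <- matrix(0, n, n, dimnames = list(p$iid, p$iid))
  for (i in seq_len(n)) for (j in seq_len(i))
    A[i, j] <- A[j, i] <- 2 * phi(i, j)
  A
}

# GRM by a literal double loop over individual pairs and SNPs
grmOracle <- function(g) {
  n <- nrow(g); m <- ncol(g)
  p <- colMeans(g, na.rm = TRUE) / 2
  A <- matrix(0, n, n, dimnames = list(rownames(g), rownames(g)))
  for (j in seq_len(n)) for (k in seq_len(j)) {
    s <- 0; cnt <- 0
    for (i in seq_len(m)) {
      xj <- g[j, i]; xk <- g[k, i]
      if (!is.na(xj) && !is.na(xk)) {
        s <- s + (xj - 2 * p[i]) * (xk - 2 * p[i]) /
          (2 * p[i] * (1 - p[i]))
        cnt <- cnt + 1
      }
    }
    A[j, k] <- A[k, j] <- s / cnt
  }
  A
}

# exhaustive clumping: recompute the full r^2 matrix and apply the
# greedy rule directly on it
clumpOracle <- function(stats, g, r2Max = 0.1, windowKb = 250) {
  st <- stats[stats$snp %in% colnames(g), , drop = FALSE]
  R2 <- suppressWarnings(cor(g[, st$snp, drop = FALSE]))^2
  R2[is.na(R2)] <- 0
  alive <- rep(TRUE, nrow(st))
  keep <- logical(nrow(st))
  ord <- order(st$p, st$chr, st$bp)
  for (i in ord) {
    if (!alive[i]) next
    keep[i] <- TRUE
    alive[i] <- FALSE
    drop <- alive & st$chr == st$chr[i] &
      abs(st$bp - st$bp[i]) <= windowKb * 1000 & R2[i, ] > r2Max
    alive[drop] <- FALSE
  }
  sort(st$snp[keep])
}

# exact HWE p by direct enumeration with log-multinomial weights
hweOracle <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  hets <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
  lp <- vapply(hets, function(h) {
    na2 <- (nA - h) / 2
    nb2 <- n - h - na2
    if (na2 < 0 || nb2 < 0) return(-Inf)
    lfactorial(n) - lfactorial(na2) - lfactorial(h) - lfactorial(nb2) +
      h * log(2) + lfactorial(nA) + lfactorial(2 * n - nA) -
      lfactorial(2 * n)
  }, numeric(1))
  pr <- exp(lp - max(lp)); pr <- pr / sum(pr)
  sum(pr[pr <= pr[match(nAa, hets)] + 1e-12])
}

# hand-built three-generation pedigree with grandparents, an avuncular
# link and first cousins (spouses married into the family are founders)
threeGenPedigree <- function() {
  df <- data.frame(
    fid = "F1",
    iid = c("gpa", "gma", "s1", "s2", "w1", "w2", "c1", "c2"),
    pat = c("0", "0", "gpa", "gpa", "0", "0", "s1", "s2"),
    mat = c("0", "0", "gma", "gma", "0", "0", "w1", "w2"),
    sex = c(1L, 2L, 1L, 1L, 2L, 2L, 1L, 2L),
    couple = c("cpG", "cpG", "cp1", "cp2", "cp1", "cp2", "0", "0"),
    stringsAsFactors = FALSE)
  new("Pedigree", ped = df)
}

# tiny genotype container from a plain matrix (1-based positions)
makeGenotypeMatrix <- function(g, chr = NULL, bp = NULL,
                               a1 = "A", a2 = "G") {
  m <- ncol(g)
  if (is.null(rownames(g))) rownames(g) <- paste0("i", seq_len(nrow(g)))
  if (is.null(colnames(g))) colnames(g) <- paste0("s", seq_len(m))
  map <- data.frame(snp = colnames(g),
                    chr = if (is.null(chr)) rep(1L, m) else chr,
                    bp = if (is.null(bp)) seq_len(m) * 1000L else bp,
                    a1 = rep_len(a1, m), a2 = rep_len(a2, m),
                    stringsAsFactors = FALSE)
  new("GenotypeMatrix", genotypes = g, map = map)
}
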