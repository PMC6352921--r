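#' Simulate a cohort of nuclear families
#'
#' Generates a pedigree of \code{nCouples} founder couples, each with a
#' sibship size drawn from \code{sibshipDist}, plus \code{nSingletons}
#' unrelated founders.  Couples are always founders (no remarriage, no
#' half-siblings); each couple and its children form one nuclear family,
#' and singletons are single-member families.
#'
#' @param nCouples number of founder couples.
#' @param sibshipDist distribution over sibship sizes: a named numeric
#'   vector of probabilities whose names are non-negative integer sizes
#'   (e.g. \code{c("0" = .2, "2" = .5, "3" = .3)}), or a single
#'   non-negative integer for a fixed sibship size.
#' @param nSingletons number of unrelated singleton founders.
#' @param seed integer seed; the generator is bit-reproducible given it.
#' @return a [Pedigree-class] object.
#' @examples
#' ped <- simulatePedigree(5, sibshipDist = 2, nSingletons = 3, seed = 1)
#' pedigreeCounts(ped)
#' @export
simulatePedigree <- function(nCouples, sibshipDist = 2, nSingletons = 0,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (nCouples < 0 || nSingletons < 0)
    stop("nCouples and nSingletons must be non-negative")
  if (length(sibshipDist) == 1L && is.null(names(sibshipDist))) {
    sizes <- as.integer(sibshipDist)
    if (is.na(sizes) || sizes < 0) stop("invalid sibship distribution")
    probs <- 1
  } else {
    sizes <- suppressWarnings(as.integer(names(sibshipDist)))
    probs <- as.numeric(sibshipDist)
    if (any(is.na(sizes)) || any(sizes < 0) || any(probs < 0) ||
        sum(probs) <= 0)
      stop("invalid sibship distribution: names must be non-negative ",
           "integer sizes with non-negative probabilities")
    probs <- probs / sum(probs)
  }

  rows <- vector("list", nCouples + 1L)
  if (nCouples > 0) {
    nKids <- if (length(sizes) == 1L) rep(sizes, nCouples) else
      sample(sizes, nCouples, replace = TRUE, prob = probs)
    for (f in seq_len(nCouples)) {
      fid <- sprintf("F%04d", f)
      fa <- paste0(fid, "_P1"); mo <- paste0(fid, "_P2")
      cid <- sprintf("CP%04d", f)
      kids <- if (nKids[f] > 0) {
        data.frame(fid = fid,
                   iid = paste0(fid, "_C", seq_len(nKids[f])),
                   pat = fa, mat = mo,
                   sex = sample(1:2, nKids[f], replace = TRUE),
                   couple = "0", stringsAsFactors = FALSE)
      } else NULL
      rows[[f]] <- rbind(
        data.frame(fid = fid, iid = c(fa, mo), pat = "0", mat = "0",
                   sex = c(1L, 2L), couple = cid,
                   stringsAsFactors = FALSE),
        kids)
    }
  }
  if (nSingletons > 0) {
    rows[[nCouples + 1L]] <- data.frame(
      fid = sprintf("S%04d", seq_len(nSingletons)),
      iid = sprintf("S%04d_I", seq_len(nSingletons)),
      pat = "0", mat = "0",
      sex = sample(1:2, nSingletons, replace = TRUE),
      couple = "0", stringsAsFactors = FALSE)
  }
  ped <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(ped) || nrow(ped) == 0) stop("empty pedigree requested")
  rownames(ped) <- NULL
  new("Pedigree", ped = ped)
}

#' Summary counts of a pedigree
#'
#' Counts the relationships that drive the couple, sibling and family
#' covariance structures: spouse pairs, full-sibling pairs, and nuclear
#' families containing at least two members.
#'
#' @param ped a [Pedigree-class].
#' @return list with \code{nIndividuals}, \code{nCouples},
#'   \code{nSibPairs}, \code{nNuclearFamilies}.
#' @export
pedigreeCounts <- function(ped) {
  p <- ped@ped
  cp <- table(p$couple[p$couple != "0"])
  sib <- p[p$pat != "0", ]
  sibSizes <- if (nrow(sib)) table(paste(sib$pat, sib$mat)) else integer(0)
  famSizes <- table(p$fid)
  list(nIndividuals = nrow(p),
       nCouples = sum(cp == 2),
       nSibPairs = sum(choose(as.integer(sibSizes), 2)),
       nNuclearFamilies = sum(famSizes >= 2))
}

# Topologically sort so parents precede children; error on cycles.
# Returns the permutation of row indices (identity when the table is
# already parents-first, so callers can skip reordering copies).
sortPedigreeOrder <- function(p) {
  n <- nrow(p)
  idx <- seq_len(n)
  fpos <- match(p$pat, p$iid, nomatch = 0L)
  mpos <- match(p$mat, p$iid, nomatch = 0L)
  if (all(fpos < idx) && all(mpos < idx)) return(idx)
  pos <- match(p$pat, p$iid)  # NA for founders
  pos2 <- match(p$mat, p$iid)
  placed <- logical(n)
  out <- integer(0)
  repeat {
    ready <- !placed &
      (is.na(pos) | placed[ifelse(is.na(pos), 1L, pos)]) &
      (is.na(pos2) | placed[ifelse(is.na(pos2), 1L, pos2)])
    if (!any(ready)) break
    out <- c(out, idx[ready])
    placed[ready] <- TRUE
  }
  if (length(out) < n)
    stop("pedigree contains a cycle (an individual is its own ancestor)")
  out
}
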