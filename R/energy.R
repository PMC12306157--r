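#' Infer the stem-loop structure of an arm pair
#'
#' Pairs the left arm against the right arm anti-parallel, outside-in,
#' classifying each position as \code{GC}, \code{AT} or \code{GT}
#' (order-insensitive) and anything else as \code{MISMATCH}.  Bulge
#' positions recorded during assembly contribute \code{GAP} entries and
#' are skipped on their own arm.
#'
#' @param pair a one-row arm-pair \code{data.frame} (see
#'   \code{\link{assemblePairs}}).
#' @param regionSeq the DNA string the coordinates refer to.
#' @return an unscored \code{\linkS4class{Hairpin}}.
#' @examples
#' p <- assemblePairs(extendPair(c(3, 8, 15, 20),
#'   paste0("AA", "GCCGGAT", "TTTT", "ATCCGGC", "AA")))
#' inferStructure(p, paste0("AA", "GCCGGAT", "TTTT", "ATCCGGC", "AA"))
#' @export
inferStructure <- function(pair, regionSeq) {
  stopifnot(is.data.frame(pair), nrow(pair) == 1L)
  ls <- pair$ls; le <- pair$le; rs <- pair$rs; re <- pair$re
  if (le < ls || re < rs) stop("zero-length arm")
  bases <- strsplit(regionSeq, "", fixed = TRUE)[[1L]]
  gapL <- pair$gapL[[1L]]; gapR <- pair$gapR[[1L]]
  i <- ls; j <- re
  stem <- character()
  while (i <= le || j >= rs) {
    if (i <= le && i %in% gapL) {
      stem <- c(stem, "GAP"); i <- i + 1L
    } else if (j >= rs && j %in% gapR) {
      stem <- c(stem, "GAP"); j <- j - 1L
    } else if (i > le) {
      stem <- c(stem, "GAP"); j <- j - 1L
    } else if (j < rs) {
      stem <- c(stem, "GAP"); i <- i + 1L
    } else {
      stem <- c(stem, .pairClass(bases[i], bases[j]))
      i <- i + 1L; j <- j - 1L
    }
  }
  new("Hairpin", leftStart = as.integer(ls), leftEnd = as.integer(le),
      rightStart = as.integer(rs), rightEnd = as.integer(re),
      stem = stem, loopLen = as.integer(rs - le - 1L),
      energy = NA_real_)
}

#' Score a hairpin with the additive energy model
#'
#' Sums per-position pair energies/penalties over the stem and adds the
#' linear loop penalty \code{loopCoeff * (loopLen - loopOffset)}.  The
#' loop term is applied as written even for loops shorter than the
#' offset; structural admissibility is governed by the filters, not the
#' energy term.
#'
#' @param h a \code{\linkS4class{Hairpin}}.
#' @param model an \code{\link{energyModel}}.
#' @return the scored \code{Hairpin} (energy in kcal/mol; more negative =
#'   more stable).
#' @examples
#' h <- new("Hairpin", leftStart = 1L, leftEnd = 4L, rightStart = 9L,
#'          rightEnd = 12L, stem = rep("GC", 4), loopLen = 4L,
#'          energy = NA_real_)
#' hairpinEnergy(scoreHairpin(h))  # 4 * -2.3 + (4 - 2) = -7.2
#' @export
scoreHairpin <- function(h, model = energyModel()) {
  e <- c(GC = model@eGC, AT = model@eAT, GT = model@eGT,
         MISMATCH = model@mismatchPen, GAP = model@gapPen)
  h@energy <- sum(e[h@stem]) +
    model@loopCoeff * (h@loopLen - model@loopOffset)
  h
}

#' @rdname scoreHairpin
#' @return \code{hairpinEnergy} returns the stored energy (kcal/mol).
#' @export
hairpinEnergy <- function(h) h@energy

#' Does a hairpin pass the stability cutoff?
#'
#' @param h a scored \code{\linkS4class{Hairpin}}.
#' @param model an \code{\link{energyModel}}.
#' @return \code{TRUE} iff the energy is at or below
#'   \code{hairpinCutoff} (inclusive).
#' @export
passesEnergy <- function(h, model = energyModel()) {
  if (is.na(h@energy)) stop("hairpin is not scored")
  h@energy <= model@hairpinCutoff
}
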