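#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame
NULL

#' Scan configuration
#'
#' Holds every tunable structural parameter of the palindrome scan.  The
#' defaults are calibrated against the annotated REP complement of
#' \emph{E. coli} and are the values a typical genome-wide run uses.
#'
#' @slot k k-mer size used for seeding (nt).
#' @slot maxSpan maximum outer span of a seed pair, i.e. distance from the
#'   first base of the left k-mer to the last base of the right k-mer (nt).
#' @slot spanMode how \code{maxSpan} is measured: \code{"outer"} (outer
#'   span, default) or \code{"start"} (difference of start positions).
#' @slot maxGap maximum bulge length bridged when adjacent extended pairs
#'   are assembled into one stem (nt).
#' @slot minArm,maxArm admissible stem arm length range (nt).
#' @slot maxLoop maximum loop length (nt).
#' @slot minStem minimum number of paired stem positions.
#' @slot minStemLoopRatio minimum ratio of paired stem positions to loop
#'   length.
#' @slot maxGeneDistance maximum gap between a candidate and its upstream
#'   gene (nt); candidates further away are dropped during annotation.
#' @slot minElementLen minimum whole-element length (nt).
#' @slot stopProximity distance from an upstream same-strand stop codon at
#'   or below which a candidate is flagged as a putative translational
#'   regulator (nt).
#' @slot keepEdge keep candidates that have no upstream gene on their
#'   sequence record (record edges)?
#' @export
setClass("ScanConfig",
  representation(
    k = "integer", maxSpan = "integer", spanMode = "character",
    maxGap = "integer", minArm = "integer", maxArm = "integer",
    maxLoop = "integer", minStem = "integer",
    minStemLoopRatio = "numeric", maxGeneDistance = "integer",
    minElementLen = "integer", stopProximity = "integer",
    keepEdge = "logical"))

setValidity("ScanConfig", function(object) {
  msg <- character()
  if (object@k < 2L) msg <- c(msg, "k must be >= 2")
  if (object@maxSpan < 2L * object@k)
    msg <- c(msg, "maxSpan must be >= 2*k")
  if (!object@spanMode %in% c("outer", "start"))
    msg <- c(msg, "spanMode must be 'outer' or 'start'")
  if (object@maxGap < 0L) msg <- c(msg, "maxGap must be >= 0")
  lens <- c(object@minArm, object@maxArm, object@maxLoop, object@minStem,
            object@minElementLen)
  if (any(lens < 1L)) msg <- c(msg, "length parameters must be positive")
  if (object@minArm > object@maxArm) msg <- c(msg, "minArm > maxArm")
  if (object@minStemLoopRatio <= 0)
    msg <- c(msg, "minStemLoopRatio must be > 0")
  if (length(msg)) msg else TRUE
})

#' @param k,maxSpan,spanMode,maxGap,minArm,maxArm,maxLoop,minStem
#'   see slot documentation.
#' @param minStemLoopRatio,maxGeneDistance,minElementLen,stopProximity,keepEdge
#'   see slot documentation.
#' @return \code{scanConfig()} returns a validated \code{ScanConfig}.
#' @examples
#' scanConfig()
#' scanConfig(maxGeneDistance = 6200L)  # settings for a full-genome run
#' @rdname ScanConfig-class
#' @export
scanConfig <- function(k = 6L, maxSpan = 50L, spanMode = "outer",
                       maxGap = 2L, minArm = 5L, maxArm = 32L,
                       maxLoop = 11L, minStem = 1L,
                       minStemLoopRatio = 0.2, maxGeneDistance = 200L,
                       minElementLen = 10L, stopProximity = 15L,
                       keepEdge = FALSE) {
  new("ScanConfig", k = as.integer(k), maxSpan = as.integer(maxSpan),
      spanMode = spanMode, maxGap = as.integer(maxGap),
      minArm = as.integer(minArm), maxArm = as.integer(maxArm),
      maxLoop = as.integer(maxLoop), minStem = as.integer(minStem),
      minStemLoopRatio = minStemLoopRatio,
      maxGeneDistance = as.integer(maxGeneDistance),
      minElementLen = as.integer(minElementLen),
      stopProximity = as.integer(stopProximity),
      keepEdge = isTRUE(keepEdge))
}

#' Additive hairpin energy model
#'
#' Per-pair energies and penalties (kcal/mol) for stem-loop scoring, with a
#' linear loop penalty \code{loopCoeff * (loopLen - loopOffset)}.  Negative
#' totals indicate stable hairpins; candidates must score at or below
#' \code{hairpinCutoff}.
#'
#' @slot eGC,eAT,eGT pair energies for G-C, A-T and G-T wobble pairs.
#' @slot mismatchPen,gapPen penalties for mismatched and bulged positions.
#' @slot loopCoeff,loopOffset loop penalty parameters.
#' @slot hairpinCutoff maximum (least negative) admissible hairpin energy.
#' @export
setClass("EnergyModel",
  representation(
    eGC = "numeric", eAT = "numeric", eGT = "numeric",
    mismatchPen = "numeric", gapPen = "numeric",
    loopCoeff = "numeric", loopOffset = "numeric",
    hairpinCutoff = "numeric"))

setValidity("EnergyModel", function(object) {
  ok <- object@eGC < object@eAT && object@eAT < 0 && object@eGT > 0 &&
    object@eGT < object@mismatchPen && object@mismatchPen < object@gapPen
  if (ok) TRUE else
    "expected eGC < eAT < 0 < eGT < mismatchPen < gapPen"
})

#' @param eGC,eAT,eGT,mismatchPen,gapPen,loopCoeff,loopOffset,hairpinCutoff
#'   see slot documentation.
#' @return \code{energyModel()} returns a validated \code{EnergyModel}.
#' @examples
#' energyModel()
#' @rdname EnergyModel-class
#' @export
energyModel <- function(eGC = -2.3, eAT = -0.9, eGT = 1.3,
                        mismatchPen = 3.5, gapPen = 6.0,
                        loopCoeff = 1, loopOffset = 2,
                        hairpinCutoff = -0.2) {
  new("EnergyModel", eGC = eGC, eAT = eAT, eGT = eGT,
      mismatchPen = mismatchPen, gapPen = gapPen, loopCoeff = loopCoeff,
      loopOffset = loopOffset, hairpinCutoff = hairpinCutoff)
}

#' Thymine-tail model for terminator classification
#'
#' Parameters of the weighted tail score applied to the up-to-\code{window}
#' bases immediately 3' of a hairpin.  Thymines weigh \code{wT}, all other
#' bases \code{wOther}; tails scoring at or below \code{tailCutoff} mark
#' the element as a Rho-independent terminator (RIT).
#'
#' @slot window tail window length (nt).
#' @slot wT,wOther per-base weights for T and non-T bases.
#' @slot tailCutoff RIT classification threshold (inclusive).
#' @export
setClass("TailModel",
  representation(window = "integer", wT = "numeric", wOther = "numeric",
                 tailCutoff = "numeric"))

setValidity("TailModel", function(object) {
  msg <- character()
  if (object@window < 1L) msg <- c(msg, "window must be >= 1")
  if (!(object@wOther > 0 && object@wOther < object@wT && object@wT < 1))
    msg <- c(msg, "expected 0 < wOther < wT < 1")
  if (length(msg)) msg else TRUE
})

#' @param window,wT,wOther,tailCutoff see slot documentation.
#' @return \code{tailModel()} returns a validated \code{TailModel}.
#' @examples
#' tailModel()
#' @rdname TailModel-class
#' @export
tailModel <- function(window = 15L, wT = 0.9, wOther = 0.6,
                      tailCutoff = -2.5) {
  new("TailModel", window = as.integer(window), wT = wT, wOther = wOther,
      tailCutoff = tailCutoff)
}

#' Inferred stem-loop structure
#'
#' The structure implied by one arm pair: an ordered list of stem position
#' classes (outside-in) plus the loop length and, once scored, the hairpin
#' energy.  Coordinates are 1-based inclusive within the scanned sequence.
#'
#' @slot leftStart,leftEnd,rightStart,rightEnd arm coordinates.
#' @slot stem character vector over \code{GC, AT, GT, MISMATCH, GAP}.
#' @slot loopLen loop length (nt).
#' @slot energy hairpin energy (kcal/mol); \code{NA} until scored.
#' @export
setClass("Hairpin",
  representation(leftStart = "integer", leftEnd = "integer",
                 rightStart = "integer", rightEnd = "integer",
                 stem = "character", loopLen = "integer",
                 energy = "numeric"))

setValidity("Hairpin", function(object) {
  msg <- character()
  if (length(object@stem) < 1L) msg <- c(msg, "stem must have length >= 1")
  if (!all(object@stem %in% c("GC", "AT", "GT", "MISMATCH", "GAP")))
    msg <- c(msg, "unknown stem pair class")
  if (object@loopLen != object@rightStart - object@leftEnd - 1L)
    msg <- c(msg, "loopLen inconsistent with arm coordinates")
  if (length(msg)) msg else TRUE
})

#' Result of a palindromic-element scan
#'
#' Container bundling the annotated candidate \code{GRanges} with the run
#' summary and the parameter objects that produced it.
#'
#' @slot candidates \code{GRanges} of classified, annotated elements.
#' @slot summary list with totals, length histogram, group counts and
#'   per-window densities.
#' @slot config,energy,tail the parameter objects used.
#' @export
setClass("PEScanResult",
  representation(candidates = "GRanges", summary = "list",
                 config = "ScanConfig", energy = "EnergyModel",
                 tail = "TailModel"))

#' @export
setGeneric("candidates", function(x) standardGeneric("candidates"))

#' Extract the candidate table of a scan result
#' @param x a \code{PEScanResult}.
#' @return a \code{GRanges} of candidates.
#' @rdname PEScanResult-class
#' @export
setMethod("candidates", "PEScanResult", function(x) x@candidates)

#' @export
setGeneric("scanSummary", function(x) standardGeneric("scanSummary"))

#' Extract the run summary of a scan result
#' @rdname PEScanResult-class
#' @export
setMethod("scanSummary", "PEScanResult", function(x) x@summary)

setMethod("show", "PEScanResult", function(object) {
  s <- object@summary
  cat("PEScanResult:", s$n_total, "palindromic elements (",
      s$n_rep, "REP /", s$n_rit, "RIT )\n")
  if (s$n_rep > 0L)
    cat("  REPs <=", object@config@stopProximity,
        "nt from an upstream stop codon:", s$group1,
        "; further away:", s$group2, "\n")
  if (s$n_total > 0L) {
    w <- GenomicRanges::width(object@candidates)
    cat("  element lengths:", min(w), "-", max(w), "nt\n")
  }
  invisible(object)
})

setMethod("show", "ScanConfig", function(object) {
  cat("ScanConfig: k=", object@k, " maxSpan=", object@maxSpan,
      " (", object@spanMode, ") maxGap=", object@maxGap,
      " arm=[", object@minArm, ",", object@maxArm, "] maxLoop=",
      object@maxLoop, " minStem=", object@minStem, " ratio>=",
      object@minStemLoopRatio, "\n  maxGeneDistance=",
      object@maxGeneDistance, " minElementLen=", object@minElementLen,
      " stopProximity=", object@stopProximity, "\n", sep = "")
  invisible(object)
})

setMethod("show", "Hairpin", function(object) {
  cat("Hairpin: arms [", object@leftStart, "-", object@leftEnd, "] / [",
      object@rightStart, "-", object@rightEnd, "], loop ", object@loopLen,
      " nt, stem ", paste(object@stem, collapse = " "),
      if (!is.na(object@energy)) paste0(", energy ", object@energy) else "",
      "\n", sep = "")
  invisible(object)
})
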