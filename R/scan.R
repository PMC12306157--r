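#' Positioned k-mers of a sequence
#'
#' Decomposes a sequence into its overlapping k-mers with 1-based start
#' offsets.  K-mers containing \code{N} are flagged non-seedable and never
#' participate in seeding.
#'
#' @param regionSeq a DNA string.
#' @param k k-mer size (>= 2).
#' @return a \code{data.frame} with columns \code{offset}, \code{kmer},
#'   \code{seedable}; empty for sequences shorter than \code{k}.
#' @export
kmerize <- function(regionSeq, k = 6L) {
  stopifnot(k >= 2L)
  L <- nchar(regionSeq)
  if (L < k)
    return(data.frame(offset = integer(), kmer = character(),
                      seedable = logical()))
  starts <- seq_len(L - k + 1L)
  kmers <- substring(regionSeq, starts, starts + k - 1L)
  data.frame(offset = starts, kmer = kmers,
             seedable = !grepl("N", kmers, fixed = TRUE))
}

# empty arm-pair frame; gapL/gapR hold bulge positions recorded by assembly
.emptyPairs <- function() {
  data.frame(ls = integer(), le = integer(), rs = integer(),
             re = integer(), gapL = I(list()), gapR = I(list()))
}

.pairFrame <- function(ls, le, rs, re) {
  n <- length(ls)
  data.frame(ls = ls, le = le, rs = rs, re = re,
             gapL = I(replicate(n, integer(), simplify = FALSE)),
             gapR = I(replicate(n, integer(), simplify = FALSE)))
}

#' Find palindromic seed pairs
#'
#' Identifies all ordered position pairs (i, j) whose k-mers are exact
#' reverse complements, whose arms do not overlap, and whose span is
#' within \code{maxSpan} of the configuration (outer span by default).
#'
#' @param regionSeq a DNA string.
#' @param cfg a \code{\link{scanConfig}}.
#' @return an arm-pair \code{data.frame} with 1-based inclusive columns
#'   \code{ls, le, rs, re}, ordered by (ls, rs).
#' @examples
#' seedSeq <- paste0("AA", "GCCGGAT", "TTTT", "ATCCGGC", "AA")
#' findSeedPairs(seedSeq, scanConfig())
#' @export
findSeedPairs <- function(regionSeq, cfg = scanConfig()) {
  k <- cfg@k
  km <- kmerize(regionSeq, k)
  if (!nrow(km)) return(.emptyPairs())
  L <- nchar(regionSeq)
  rcSeq <- .revcompChar(regionSeq)
  # reverse complement of the k-mer at i is a substring of the reverse
  # complement of the whole sequence
  rcKmer <- substring(rcSeq, L - (km$offset + k - 1L) + 1L,
                      L - km$offset + 1L)
  seedable <- km$seedable
  posByKmer <- split(km$offset[seedable], km$kmer[seedable])
  resI <- integer(); resJ <- integer()
  for (idx in which(seedable)) {
    i <- km$offset[idx]
    js <- posByKmer[[rcKmer[idx]]]
    if (is.null(js)) next
    jmax <- if (cfg@spanMode == "outer") i + cfg@maxSpan - k else
      i + cfg@maxSpan
    js <- js[js >= i + k & js <= jmax]
    if (length(js)) {
      resI <- c(resI, rep.int(i, length(js)))
      resJ <- c(resJ, js)
    }
  }
  if (!length(resI)) return(.emptyPairs())
  ord <- order(resI, resJ)
  .pairFrame(resI[ord], resI[ord] + k - 1L, resJ[ord], resJ[ord] + k - 1L)
}

# core extension on a pre-split character vector
.extend <- function(bases, ls, le, rs, re) {
  L <- length(bases)
  repeat {
    grew <- FALSE
    if (rs - le - 1L >= 2L && .isPair(bases[le + 1L], bases[rs - 1L])) {
      le <- le + 1L; rs <- rs - 1L; grew <- TRUE
    }
    if (ls > 1L && re < L && .isPair(bases[ls - 1L], bases[re + 1L])) {
      ls <- ls - 1L; re <- re + 1L; grew <- TRUE
    }
    if (!grew) break
  }
  c(ls, le, rs, re)
}

#' Extend a seed pair to its maximal arm pair
#'
#' Grows the arms of a seed pair symmetrically inward and outward while
#' the newly added base pair is Watson-Crick (A-T, G-C) or G-T wobble, the
#' arms do not cross, and sequence bounds are respected.
#'
#' @param pair a one-row arm-pair \code{data.frame} (or a numeric vector
#'   \code{c(ls, le, rs, re)}).
#' @param regionSeq the DNA string the coordinates refer to.
#' @return the maximally extended arm pair, same shape as the input row.
#' @export
extendPair <- function(pair, regionSeq) {
  if (is.data.frame(pair)) {
    stopifnot(nrow(pair) == 1L)
    v <- c(pair$ls, pair$le, pair$rs, pair$re)
  } else v <- as.integer(pair)
  bases <- strsplit(regionSeq, "", fixed = TRUE)[[1L]]
  out <- .extend(bases, v[1L], v[2L], v[3L], v[4L])
  .pairFrame(out[1L], out[2L], out[3L], out[4L])
}

.dedupPairs <- function(pairs) {
  if (!nrow(pairs)) return(pairs)
  key <- paste(pairs$ls, pairs$le, pairs$rs, pairs$re)
  pairs[!duplicated(key), , drop = FALSE]
}

# drop pairs whose both arms lie inside another pair's arms
.dropContained <- function(pairs) {
  n <- nrow(pairs)
  if (n < 2L) return(pairs)
  keep <- rep(TRUE, n)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (a == b || !keep[a]) next
      if (pairs$ls[b] <= pairs$ls[a] && pairs$le[a] <= pairs$le[b] &&
          pairs$rs[b] <= pairs$rs[a] && pairs$re[a] <= pairs$re[b] &&
          !(pairs$ls[b] == pairs$ls[a] && pairs$le[b] == pairs$le[a] &&
            pairs$rs[b] == pairs$rs[a] && pairs$re[b] == pairs$re[a])) {
        keep[a] <- FALSE
        break
      }
    }
  }
  pairs[keep, , drop = FALSE]
}

#' Assemble adjacent arm pairs across short bulges
#'
#' Merges two extended arm pairs into one stem when their left arms and
#' their right arms are each separated by at most \code{maxGap} unpaired
#' bases; the bulged positions are recorded as gaps and later priced by
#' the energy model.  Merging repeats to a fixed point; the result is
#' deduplicated and maximal (no output pair strictly contained in
#' another).
#'
#' @param pairs an arm-pair \code{data.frame} (extension already applied),
#'   all from one scanned sequence.
#' @param cfg a \code{\link{scanConfig}}.
#' @return the assembled arm-pair \code{data.frame}, ordered by (ls, rs),
#'   with bulge positions in the \code{gapL}/\code{gapR} list columns.
#' @export
assemblePairs <- function(pairs, cfg = scanConfig()) {
  pairs <- .dedupPairs(pairs)
  if (nrow(pairs) < 2L) return(pairs)
  maxGap <- cfg@maxGap
  repeat {
    pairs <- pairs[order(pairs$ls, pairs$rs), , drop = FALSE]
    rownames(pairs) <- NULL
    n <- nrow(pairs)
    mergedAny <- FALSE
    for (a in seq_len(n)) {
      for (b in seq_len(n)) {
        if (a == b) next
        # b must be the inner pair, nested between a's arms
        gl <- pairs$ls[b] - pairs$le[a] - 1L
        gr <- pairs$rs[a] - pairs$re[b] - 1L
        if (gl < 0L || gl > maxGap || gr < 0L || gr > maxGap) next
        gapL <- sort(unique(c(pairs$gapL[[a]], pairs$gapL[[b]],
          if (gl > 0L) seq.int(pairs$le[a] + 1L, pairs$ls[b] - 1L))))
        gapR <- sort(unique(c(pairs$gapR[[a]], pairs$gapR[[b]],
          if (gr > 0L) seq.int(pairs$re[b] + 1L, pairs$rs[a] - 1L))))
        merged <- data.frame(ls = pairs$ls[a], le = pairs$le[b],
                             rs = pairs$rs[b], re = pairs$re[a],
                             gapL = I(list(gapL)), gapR = I(list(gapR)))
        pairs <- rbind(pairs[-c(a, b), , drop = FALSE], merged)
        mergedAny <- TRUE
        break
      }
      if (mergedAny) break
    }
    if (!mergedAny) break
  }
  pairs <- .dropContained(.dedupPairs(pairs))
  pairs <- pairs[order(pairs$ls, pairs$rs), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

# full scan of one sequence in one orientation: seeds -> extension ->
# dedup -> assembly
.scanSequence <- function(regionSeq, cfg) {
  seeds <- findSeedPairs(regionSeq, cfg)
  if (!nrow(seeds)) return(seeds)
  bases <- strsplit(regionSeq, "", fixed = TRUE)[[1L]]
  ext <- t(vapply(seq_len(nrow(seeds)), function(i)
    .extend(bases, seeds$ls[i], seeds$le[i], seeds$rs[i], seeds$re[i]),
    integer(4L)))
  pairs <- .pairFrame(ext[, 1L], ext[, 2L], ext[, 3L], ext[, 4L])
  assemblePairs(.dedupPairs(pairs), cfg)
}
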