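#' Structural admissibility of a scored hairpin
#'
#' Checks every structural filter of the method: arm length within
#' [\code{minArm}, \code{maxArm}], loop length at most \code{maxLoop},
#' at least \code{minStem} paired stem positions, stem-to-loop ratio at
#' least \code{minStemLoopRatio}, whole-element length at least
#' \code{minElementLen}, and the hairpin energy cutoff.  All thresholds
#' are inclusive.
#'
#' @param h a scored \code{\linkS4class{Hairpin}}.
#' @param cfg a \code{\link{scanConfig}}.
#' @param model the \code{\link{energyModel}} used for the energy cutoff.
#' @return \code{TRUE} iff all filters hold.
#' @export
applyStructuralFilters <- function(h, cfg = scanConfig(),
                                   model = energyModel()) {
  armL <- h@leftEnd - h@leftStart + 1L
  armR <- h@rightEnd - h@rightStart + 1L
  stemLen <- sum(h@stem != "GAP")
  elementLen <- h@rightEnd - h@leftStart + 1L
  min(armL, armR) >= cfg@minArm && max(armL, armR) <= cfg@maxArm &&
    h@loopLen <= cfg@maxLoop && stemLen >= cfg@minStem &&
    stemLen / max(h@loopLen, 1L) >= cfg@minStemLoopRatio &&
    elementLen >= cfg@minElementLen && passesEnergy(h, model)
}

# scan one orientation of one region sequence and return the surviving,
# classified candidates in scan-orientation coordinates
.orientationCandidates <- function(seqStr, cfg, em, tm) {
  pairs <- .scanSequence(seqStr, cfg)
  if (!nrow(pairs)) return(NULL)
  L <- nchar(seqStr)
  keep <- logical(nrow(pairs))
  stemLen <- integer(nrow(pairs)); loopLen <- integer(nrow(pairs))
  energy <- numeric(nrow(pairs)); tailSc <- numeric(nrow(pairs))
  type <- character(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    h <- scoreHairpin(inferStructure(pairs[i, , drop = FALSE], seqStr), em)
    if (!applyStructuralFilters(h, cfg, em)) next
    tail <- if (pairs$re[i] < L)
      substring(seqStr, pairs$re[i] + 1L,
                min(pairs$re[i] + tm@window, L)) else ""
    keep[i] <- TRUE
    stemLen[i] <- sum(h@stem != "GAP")
    loopLen[i] <- h@loopLen
    energy[i] <- h@energy
    tailSc[i] <- tailScore(tail, tm)
    type[i] <- classifyElement(tail, tm)
  }
  if (!any(keep)) return(NULL)
  cbind(pairs[keep, c("ls", "le", "rs", "re")],
        data.frame(stem_len = stemLen[keep], loop_len = loopLen[keep],
                   hairpin_energy = energy[keep],
                   tail_score = tailSc[keep], type = type[keep],
                   stringsAsFactors = FALSE))
}

# merge opposite-strand detections of the same physical hairpin
# (identical span, or reciprocal overlap >= minFrac).  The strand with a
# qualifying tail wins (RIT over REP); symmetric REP detections are
# reported once on "+"; double RITs keep the more negative tail score.
.collapseOrientations <- function(gr, minFrac = 0.9) {
  if (length(gr) < 2L) return(gr)
  plus <- which(as.character(strand(gr)) == "+")
  minus <- which(as.character(strand(gr)) == "-")
  if (!length(plus) || !length(minus)) return(gr)
  hits <- GenomicRanges::findOverlaps(gr[plus], gr[minus],
                                      ignore.strand = TRUE)
  if (!length(hits)) return(gr)
  qi <- plus[S4Vectors::queryHits(hits)]
  si <- minus[S4Vectors::subjectHits(hits)]
  ov <- pmin(end(gr)[qi], end(gr)[si]) - pmax(start(gr)[qi],
                                              start(gr)[si]) + 1L
  frac <- pmin(ov / width(gr)[qi], ov / width(gr)[si])
  sel <- frac >= minFrac
  qi <- qi[sel]; si <- si[sel]; ov <- ov[sel]
  drop <- logical(length(gr))
  for (h in order(-ov)) {
    a <- qi[h]; b <- si[h]          # a on "+", b on "-"
    if (drop[a] || drop[b]) next
    ta <- mcols(gr)$type[a]; tb <- mcols(gr)$type[b]
    if (ta != tb) {
      drop[if (ta == "RIT") b else a] <- TRUE
    } else if (ta == "REP") {
      drop[if (start(gr)[a] <= start(gr)[b]) b else a] <- TRUE
    } else {
      drop[if (mcols(gr)$tail_score[a] <= mcols(gr)$tail_score[b])
        b else a] <- TRUE
    }
  }
  gr[!drop]
}

#' Annotate candidates with flanking genes and stop-codon proximity
#'
#' For each candidate, records the nearest gene ending at or before its
#' start and the nearest gene starting at or after its end (forward
#' axis), with gap distances in nt (0 = adjacent).  A candidate is
#' flagged \code{within_15nt_of_stop} when a gene on the \emph{same}
#' strand has its 3' (stop-codon) end upstream of the element at a gap of
#' at most \code{stopProximity}.  Candidates whose upstream-gene gap
#' exceeds \code{maxGeneDistance} are dropped, as are edge candidates
#' without an upstream gene unless \code{keepEdge} is set.
#'
#' @param cands a candidate \code{GRanges}.
#' @param genes a gene \code{GRanges} with \code{gene_id}.
#' @param cfg a \code{\link{scanConfig}}.
#' @return the annotated, distance-filtered \code{GRanges}.
#' @export
annotateCandidates <- function(cands, genes, cfg = scanConfig()) {
  n <- length(cands)
  up <- rep(NA_character_, n); dn <- rep(NA_character_, n)
  dUp <- rep(NA_integer_, n); dDn <- rep(NA_integer_, n)
  dStop <- rep(NA_integer_, n)
  for (sid in unique(as.character(seqnames(cands)))) {
    ci <- which(as.character(seqnames(cands)) == sid)
    g <- genes[as.character(seqnames(genes)) == sid]
    if (!length(g)) next
    gid <- mcols(g)$gene_id
    gs <- start(g); ge <- end(g); gst <- as.character(strand(g))
    for (i in ci) {
      s <- start(cands)[i]; e <- end(cands)[i]
      pre <- which(ge < s)
      if (length(pre)) {
        j <- pre[which.max(ge[pre])]
        up[i] <- gid[j]; dUp[i] <- s - ge[j] - 1L
      }
      post <- which(gs > e)
      if (length(post)) {
        j <- post[which.min(gs[post])]
        dn[i] <- gid[j]; dDn[i] <- gs[j] - e - 1L
      }
      # strand-aware gap to the nearest same-strand stop codon upstream
      if (as.character(strand(cands))[i] == "+") {
        ss <- which(gst == "+" & ge < s)
        if (length(ss)) dStop[i] <- s - max(ge[ss]) - 1L
      } else {
        ss <- which(gst == "-" & gs > e)
        if (length(ss)) dStop[i] <- min(gs[ss]) - e - 1L
      }
    }
  }
  mcols(cands)$upstream_gene <- up
  mcols(cands)$dist_upstream <- dUp
  mcols(cands)$downstream_gene <- dn
  mcols(cands)$dist_downstream <- dDn
  mcols(cands)$dist_stop <- dStop
  mcols(cands)$within_15nt_of_stop <- !is.na(dStop) &
    dStop <= cfg@stopProximity
  keep <- if (cfg@keepEdge) {
    is.na(dUp) | dUp <= cfg@maxGeneDistance
  } else {
    !is.na(dUp) & dUp <= cfg@maxGeneDistance
  }
  cands[keep]
}

#' Remove redundant overlapping candidates
#'
#' Among candidates of the same type whose spans overlap by more than
#' half of the shorter span, only the one with the lowest hairpin energy
#' is kept (ties: leftmost, then longest).  Candidates of different
#' types are never deduplicated against each other.
#'
#' @param cands a candidate \code{GRanges}.
#' @return the deduplicated, sorted \code{GRanges}.
#' @export
dedupOverlaps <- function(cands) {
  if (length(cands) < 2L) return(sortCandidates(cands))
  dropAll <- logical(length(cands))
  for (ty in unique(mcols(cands)$type)) {
    idx <- which(mcols(cands)$type == ty)
    sub <- cands[idx]
    hits <- GenomicRanges::findOverlaps(sub, sub, ignore.strand = TRUE)
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    sel <- q < s
    q <- q[sel]; s <- s[sel]
    ov <- pmin(end(sub)[q], end(sub)[s]) -
      pmax(start(sub)[q], start(sub)[s]) + 1L
    conflict <- ov > 0.5 * pmin(width(sub)[q], width(sub)[s])
    q <- q[conflict]; s <- s[conflict]
    if (!length(q)) next
    pref <- order(mcols(sub)$hairpin_energy, start(sub), -width(sub))
    rank <- integer(length(sub)); rank[pref] <- seq_along(pref)
    drop <- logical(length(sub))
    for (i in pref) {
      if (drop[i]) next
      worse <- c(s[q == i], q[s == i])
      drop[worse[rank[worse] > rank[i]]] <- TRUE
    }
    dropAll[idx[drop]] <- TRUE
  }
  sortCandidates(cands[!dropAll])
}

#' Per-window strand densities
#'
#' Partitions each sequence record into consecutive windows (the last
#' window may be short) and counts candidates per (window, strand, type),
#' assigning each candidate to the window containing its start.
#'
#' @param cands a candidate \code{GRanges} with sequence lengths set (or
#'   supplied via \code{seqlens}).
#' @param window window size in nt (default 100,000).
#' @param seqlens optional named integer vector of sequence lengths.
#' @return a \code{data.frame} with columns \code{seq_id, window,
#'   window_start, window_end, strand, type, count} covering every
#'   window, including empty ones.
#' @export
windowDensity <- function(cands, window = 100000L, seqlens = NULL) {
  stopifnot(window >= 1L)
  if (is.null(seqlens)) seqlens <- seqlengths(cands)
  if (any(is.na(seqlens)))
    stop("sequence lengths are required for window densities")
  out <- list()
  for (sid in names(seqlens)) {
    L <- unname(seqlens[[sid]])
    nwin <- ceiling(L / window)
    ws <- (seq_len(nwin) - 1L) * window + 1L
    we <- pmin(seq_len(nwin) * window, L)
    grid <- expand.grid(window = seq_len(nwin), strand = c("+", "-"),
                        type = c("REP", "RIT"), stringsAsFactors = FALSE)
    grid$seq_id <- sid
    grid$window_start <- ws[grid$window]
    grid$window_end <- we[grid$window]
    ci <- which(as.character(seqnames(cands)) == sid)
    win <- (start(cands)[ci] - 1L) %/% window + 1L
    key <- paste(win, as.character(strand(cands))[ci],
                 mcols(cands)$type[ci])
    tab <- table(key)
    gkey <- paste(grid$window, grid$strand, grid$type)
    grid$count <- as.integer(tab[gkey])
    grid$count[is.na(grid$count)] <- 0L
    out[[sid]] <- grid[, c("seq_id", "window", "window_start",
                           "window_end", "strand", "type", "count")]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$seq_id, res$window, res$strand, res$type), ]
}

#' Summarize a candidate set
#'
#' Totals per class, the 1-nt-bin element length histogram, the counts of
#' REPs at most \code{stopProximity} nt from an upstream same-strand stop
#' codon (group 1) versus further away (group 2), and per-window strand
#' densities when sequence lengths are available.
#'
#' @param cands a candidate \code{GRanges} (annotated).
#' @param stopProximity group-1 distance threshold (nt).
#' @param window density window size (nt).
#' @return a list with elements \code{n_total, n_rep, n_rit, group1,
#'   group2, length_hist, density}.
#' @export
summarizeCandidates <- function(cands, stopProximity = 15L,
                                window = 100000L) {
  type <- mcols(cands)$type
  isRep <- type == "REP"
  dStop <- mcols(cands)$dist_stop
  if (is.null(dStop)) {
    # candidate set read back from TSV: only the boolean flag survives
    dStop <- ifelse(mcols(cands)$within_15nt_of_stop %in% TRUE,
                    0L, NA_integer_)
  }
  hist <- table(factor(width(cands),
                       levels = if (length(cands))
                         seq(min(width(cands)), max(width(cands)))
                       else integer()))
  dens <- if (!any(is.na(seqlengths(cands))) &&
              length(seqlengths(cands)))
    windowDensity(cands, window) else NULL
  list(n_total = length(cands), n_rep = sum(isRep),
       n_rit = sum(!isRep),
       group1 = sum(isRep & !is.na(dStop) & dStop <= stopProximity),
       group2 = sum(isRep & !is.na(dStop) & dStop > stopProximity),
       length_hist = hist, density = dens)
}

.candidateMcols <- c("type", "sequence", "stem_len", "loop_len",
                     "hairpin_energy", "tail_score")

.emptyCandidates <- function(seqinfo = NULL) {
  gr <- GRanges()
  if (!is.null(seqinfo)) GenomeInfoDb::seqinfo(gr) <- seqinfo
  mcols(gr) <- S4Vectors::DataFrame(
    type = character(), sequence = character(), stem_len = integer(),
    loop_len = integer(), hairpin_energy = numeric(),
    tail_score = numeric(), upstream_gene = character(),
    dist_upstream = integer(), downstream_gene = character(),
    dist_downstream = integer(), dist_stop = integer(),
    within_15nt_of_stop = logical())
  gr
}

#' Scan a genome for palindromic elements
#'
#' Core driver working on in-memory objects: extracts intergenic regions,
#' scans both orientations of each region (seed, extend, assemble),
#' infers and scores hairpins, applies the structural and energy filters,
#' classifies elements by tail score, collapses orientation-symmetric
#' detections, annotates against the gene set and deduplicates
#' overlapping calls.  Fully deterministic.
#'
#' @param genome a named \code{DNAStringSet} (see \code{\link{readGenome}}).
#' @param genes a gene \code{GRanges} (see \code{\link{readAnnotation}}).
#' @param cfg a \code{\link{scanConfig}}.
#' @param energy an \code{\link{energyModel}}.
#' @param tail a \code{\link{tailModel}}.
#' @return a \code{\linkS4class{PEScanResult}}.
#' @export
scanGenome <- function(genome, genes, cfg = scanConfig(),
                       energy = energyModel(), tail = tailModel()) {
  stopifnot(is(genome, "DNAStringSet"), !is.null(names(genome)))
  regions <- extractIntergenic(genes, genome, minLen = cfg@minElementLen)
  si <- Seqinfo(names(genome), unname(width(genome)))
  rows <- list()
  for (r in seq_len(length(regions))) {
    sid <- as.character(seqnames(regions))[r]
    rstart <- start(regions)[r]
    seqF <- as.character(subseq(genome[[sid]], rstart, end(regions)[r]))
    L <- nchar(seqF)
    for (ori in c("+", "-")) {
      s <- if (ori == "+") seqF else .revcompChar(seqF)
      cand <- .orientationCandidates(s, cfg, energy, tail)
      if (is.null(cand)) next
      if (ori == "+") {
        gstart <- rstart + cand$ls - 1L
        gend <- rstart + cand$re - 1L
      } else {
        gstart <- rstart + (L - cand$re)
        gend <- rstart + (L - cand$ls)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        seq_id = sid, start = gstart, end = gend, strand = ori,
        type = cand$type,
        sequence = substring(s, cand$ls, cand$re),
        stem_len = cand$stem_len, loop_len = cand$loop_len,
        hairpin_energy = cand$hairpin_energy,
        tail_score = cand$tail_score, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    cands <- .emptyCandidates(si)
  } else {
    df <- do.call(rbind, rows)
    cands <- GRanges(df$seq_id, IRanges(df$start, df$end),
                     strand = df$strand, seqinfo = si)
    mcols(cands) <- df[, .candidateMcols]
    cands <- .collapseOrientations(cands)
    cands <- annotateCandidates(cands, genes, cfg)
    cands <- dedupOverlaps(cands)
  }
  new("PEScanResult", candidates = cands,
      summary = summarizeCandidates(cands, cfg@stopProximity),
      config = cfg, energy = energy, tail = tail)
}

#' Run the full file-to-file discovery pipeline
#'
#' Reads a genome FASTA and its GFF3 annotation, runs
#' \code{\link{scanGenome}}, and (optionally) writes the TSV/BED/FASTA
#' outputs.  When the annotation contains no rows of the requested
#' feature class, \code{"CDS"} rows are used as a fallback.
#'
#' @param fasta path to the genome FASTA.
#' @param gff path to the GFF3 annotation.
#' @param cfg,energy,tail parameter objects (defaults are the standard
#'   genome-scan settings).
#' @param outPrefix if non-\code{NULL}, output path prefix passed to
#'   \code{\link{writeOutputs}}.
#' @param featureClasses GFF feature types defining genic space
#'   (default \code{"gene"}).
#' @return a \code{\linkS4class{PEScanResult}}.
#' @export
runPipeline <- function(fasta, gff, cfg = scanConfig(),
                        energy = energyModel(), tail = tailModel(),
                        outPrefix = NULL, featureClasses = "gene") {
  genome <- readGenome(fasta)
  genes <- readAnnotation(gff, featureClasses)
  if (!length(genes) && !identical(featureClasses, "CDS"))
    genes <- readAnnotation(gff, "CDS")
  res <- scanGenome(genome, genes, cfg, energy, tail)
  if (!is.null(outPrefix)) writeOutputs(candidates(res), outPrefix)
  res
}
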