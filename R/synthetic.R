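#' Random background genome
#'
#' Generates an i.i.d. random chromosome at a given GC content:
#' P(G) = P(C) = gc/2, P(A) = P(T) = (1-gc)/2.  Reproducible under a
#' fixed seed.
#'
#' @param length chromosome length (nt, >= 1000).
#' @param gc GC fraction in (0, 1); the degenerate values 0 and 1 are
#'   allowed for testing.
#' @param seed RNG seed (required: fixtures must be reproducible).
#' @param name sequence record name.
#' @return a named \code{DNAStringSet} with one record.
#' @examples
#' makeGenome(2000, gc = 0.5, seed = 1)
#' @export
makeGenome <- function(length, gc = 0.5, seed, name = "synth1") {
  stopifnot(length >= 1000L, gc >= 0, gc <= 1)
  set.seed(seed)
  bases <- sample(c("A", "C", "G", "T"), length, replace = TRUE,
                  prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  out <- DNAStringSet(paste(bases, collapse = ""))
  names(out) <- name
  out
}

#' Implant specification
#'
#' Describes a batch of identical synthetic elements to implant: REPs
#' (perfect-palindrome stem-loops, no tail) or RITs (the same hairpin
#' followed by a thymine tail).
#'
#' @param kind \code{"REP"} or \code{"RIT"}.
#' @param n how many elements of this description.
#' @param armLen stem arm length (nt).
#' @param loopLen loop length (nt).
#' @param armGC GC fraction of the randomly drawn arm.
#' @param tailLen thymine tail length for RITs (ignored for REPs).
#' @param strand strand the element is implanted on.
#' @param stopGap if not \code{NA}, the exact gap (nt) between the
#'   element and the stop-codon (3') end of its same-strand anchor gene;
#'   otherwise a gap is drawn uniformly from 20--150 nt.
#' @return a \code{data.frame} with one row per element.
#' @export
implantSpec <- function(kind = c("REP", "RIT"), n = 1L, armLen = 8L,
                        loopLen = 4L, armGC = 0.8, tailLen = 12L,
                        strand = "+", stopGap = NA_integer_) {
  kind <- match.arg(kind)
  stopifnot(strand %in% c("+", "-"), armLen >= 1L, loopLen >= 1L)
  out <- data.frame(kind = kind, armLen = as.integer(armLen),
                    loopLen = as.integer(loopLen), armGC = armGC,
                    tailLen = if (kind == "RIT") as.integer(tailLen)
                    else 0L,
                    strand = rep_len(strand, n),
                    stopGap = as.integer(stopGap),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

.sampleBases <- function(n, alphabet, prob = NULL) {
  paste(sample(alphabet, n, replace = TRUE, prob = prob), collapse = "")
}

# an arm is "clean" when it carries no alternative structure signal of
# its own: homopolymer runs are capped at 4 nt (longer runs pair by
# chance with random background runs next to the implant) and no 4-mer
# inside the arm is the reverse complement of another arm 4-mer (such
# arms fold on themselves and seed competing hairpins)
.isCleanArm <- function(arm) {
  if (grepl("(.)\\1{4,}", arm)) return(FALSE)
  n <- nchar(arm)
  if (n < 4L) return(TRUE)
  km <- substring(arm, seq_len(n - 3L), 4:n)
  rckm <- .revcompChar(km)
  !any(rckm %in% km)
}

.randomArm <- function(armLen, gc) {
  for (i in 1:100) {
    arm <- .sampleBases(armLen, c("A", "C", "G", "T"),
                        c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
    if (.isCleanArm(arm)) return(arm)
  }
  arm
}

#' Implant synthetic elements into a genome
#'
#' Lays out anchor genes at regular spacing, implants one element per
#' intergenic gap at a controlled distance from its anchor gene, and
#' returns the modified genome with the gene annotation and a ground
#' truth table.  Implants are \emph{clean}: perfect palindromic arms, an
#' all-A loop, non-pairing immediate flanks (so extension stops exactly
#' at the implanted arms), a 3' context free of T for REPs and an
#' unambiguous thymine tail for RITs, and a 5' context free of A so the
#' opposite-orientation scan cannot see a spurious T-rich tail.
#'
#' @param genome a single-record \code{DNAStringSet} background (see
#'   \code{\link{makeGenome}}).
#' @param specs a \code{data.frame} of implant rows
#'   (\code{rbind} of \code{\link{implantSpec}} calls).
#' @param geneLen anchor gene length (nt).
#' @param intergenicGap gap between consecutive anchor genes (nt).
#' @param seed RNG seed for arm/context/gap draws.
#' @param outPrefix if non-\code{NULL}, writes \code{<prefix>.fasta},
#'   \code{<prefix>.gff3} and \code{<prefix>_truth.bed} (truth BED name
#'   column = element kind).
#' @return a list with \code{genome} (modified \code{DNAStringSet}),
#'   \code{genes} (\code{GRanges} with \code{gene_id}), \code{truth}
#'   (\code{GRanges} with \code{kind} and \code{stop_gap}), and
#'   \code{paths} (written files, if any).
#' @export
implantElements <- function(genome, specs, geneLen = 1000L,
                            intergenicGap = 220L, seed,
                            outPrefix = NULL) {
  stopifnot(is(genome, "DNAStringSet"), length(genome) == 1L)
  set.seed(seed)
  # place "+" implants first so anchor-gene strand constraints never clash
  specs <- specs[order(specs$strand != "+"), , drop = FALSE]
  rownames(specs) <- NULL
  nImpl <- nrow(specs)
  nGenes <- nImpl + 1L
  sid <- names(genome)
  L <- width(genome)[1L]
  # compact gene layout with bacterial-sized intergenic gaps, so every
  # implant lies within the default upstream-gene distance bound
  spacing <- geneLen + intergenicGap
  if (100L + nGenes * spacing > L)
    stop("genome too short for ", nImpl, " implants at this layout")
  geneStart <- 100L + (seq_len(nGenes) - 1L) * spacing + 1L
  geneEnd <- geneStart + geneLen - 1L
  geneStrand <- sample(c("+", "-"), nGenes, replace = TRUE)
  bases <- strsplit(as.character(genome[[1L]]), "", fixed = TRUE)[[1L]]
  truth <- vector("list", nImpl)
  ctxLen <- 15L
  for (i in seq_len(nImpl)) {
    sp <- specs[i, ]
    g <- if (is.na(sp$stopGap)) sample(20:150, 1L) else sp$stopGap
    arm <- .randomArm(sp$armLen, sp$armGC)
    loop <- strrep("A", sp$loopLen)
    hairpin <- paste0(arm, loop, .revcompChar(arm))
    hpLen <- nchar(hairpin)
    ctxUp <- paste0(.sampleBases(ctxLen - 1L, c("C", "G", "T")), "C")
    ctxDn <- paste0("C", .sampleBases(ctxLen - 1L, c("A", "C", "G")))
    tail <- if (sp$kind == "RIT") strrep("T", sp$tailLen) else ""
    cassette <- paste0(ctxUp, hairpin, tail, ctxDn)
    if (sp$strand == "+") {
      geneStrand[i] <- "+"
      hpStart <- geneEnd[i] + g + 1L
      cs <- hpStart - ctxLen
      ce <- cs + nchar(cassette) - 1L
      if (cs <= geneEnd[i] - geneLen + 1L || ce >= geneStart[i + 1L])
        stop("insufficient intergenic space for implant spec ", i)
      span <- c(hpStart, hpStart + hpLen - 1L)
      piece <- cassette
    } else {
      geneStrand[i + 1L] <- "-"
      hpEnd <- geneStart[i + 1L] - g - 1L
      pe <- hpEnd + ctxLen
      ps <- pe - nchar(cassette) + 1L
      if (ps <= geneEnd[i] || pe >= geneStart[i + 1L] + geneLen)
        stop("insufficient intergenic space for implant spec ", i)
      span <- c(hpEnd - hpLen + 1L, hpEnd)
      piece <- .revcompChar(cassette)
      cs <- ps
    }
    bases[seq.int(cs, cs + nchar(piece) - 1L)] <-
      strsplit(piece, "", fixed = TRUE)[[1L]]
    truth[[i]] <- data.frame(start = span[1L], end = span[2L],
                             strand = sp$strand, kind = sp$kind,
                             stop_gap = g, stringsAsFactors = FALSE)
  }
  newGenome <- DNAStringSet(paste(bases, collapse = ""))
  names(newGenome) <- sid
  genes <- GRanges(sid, IRanges(geneStart, geneEnd),
                   strand = geneStrand,
                   gene_id = sprintf("g%03d", seq_len(nGenes)),
                   type = "gene",
                   seqinfo = Seqinfo(sid, L))
  td <- do.call(rbind, truth)
  truthGR <- GRanges(sid, IRanges(td$start, td$end), strand = td$strand,
                     kind = td$kind, stop_gap = td$stop_gap,
                     seqinfo = Seqinfo(sid, L))
  paths <- NULL
  if (!is.null(outPrefix)) {
    paths <- c(fasta = paste0(outPrefix, ".fasta"),
               gff = paste0(outPrefix, ".gff3"),
               bed = paste0(outPrefix, "_truth.bed"))
    writeXStringSet(newGenome, paths["fasta"])
    gffGR <- genes
    mcols(gffGR) <- S4Vectors::DataFrame(type = "gene",
                                         ID = mcols(genes)$gene_id)
    rtracklayer::export(gffGR, paths["gff"], format = "gff3")
    bedGR <- truthGR
    mcols(bedGR) <- S4Vectors::DataFrame(name = td$kind, score = 0L)
    rtracklayer::export(bedGR, paths["bed"], format = "bed")
  }
  list(genome = newGenome, genes = genes, truth = truthGR, paths = paths)
}

#' Recovery of implanted elements
#'
#' Matches predictions against a ground truth by reciprocal overlap
#' (>= 50\% of both spans), greedily by decreasing overlap with each
#' truth element and each prediction used at most once, and reports
#' recall per kind (a truth element only counts towards recall of its
#' kind when the matched prediction has that kind), overall precision,
#' kind accuracy among matched elements, and the kind confusion table.
#'
#' @param pred a candidate \code{GRanges} (or path to a candidate TSV).
#' @param truth a truth \code{GRanges} with a \code{kind} (or BED
#'   \code{name}) column, or a path to a truth BED file.
#' @return a list with \code{precision}, \code{recall} (named by kind),
#'   \code{kind_accuracy}, \code{confusion}, \code{n_pred},
#'   \code{n_truth} and the \code{matches} table.
#' @export
evaluateRecovery <- function(pred, truth) {
  if (is.character(pred)) pred <- readCandidates(pred)
  if (is.character(truth)) truth <- rtracklayer::import(truth)
  kind <- mcols(truth)$kind
  if (is.null(kind)) kind <- mcols(truth)$name
  if (is.null(kind)) stop("truth set has no kind/name column")
  predType <- mcols(pred)$type
  kinds <- sort(unique(kind))
  if (length(pred) == 0L) {
    return(list(precision = NA_real_,
                recall = stats::setNames(rep(0, length(kinds)), kinds),
                kind_accuracy = NA_real_,
                confusion = table(truth = character(),
                                  pred = character()),
                n_pred = 0L, n_truth = length(truth),
                matches = data.frame(truth_idx = integer(),
                                     pred_idx = integer(),
                                     overlap = integer())))
  }
  hits <- GenomicRanges::findOverlaps(pred, truth, ignore.strand = TRUE)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  ov <- pmin(end(pred)[q], end(truth)[s]) -
    pmax(start(pred)[q], start(truth)[s]) + 1L
  recip <- ov >= 0.5 * width(pred)[q] & ov >= 0.5 * width(truth)[s]
  q <- q[recip]; s <- s[recip]; ov <- ov[recip]
  usedP <- logical(length(pred)); usedT <- logical(length(truth))
  mT <- integer(); mP <- integer(); mOv <- integer()
  for (h in order(-ov, q)) {
    if (usedP[q[h]] || usedT[s[h]]) next
    usedP[q[h]] <- TRUE; usedT[s[h]] <- TRUE
    mT <- c(mT, s[h]); mP <- c(mP, q[h]); mOv <- c(mOv, ov[h])
  }
  recall <- vapply(kinds, function(k) {
    idx <- which(kind == k)
    if (!length(idx)) return(NA_real_)
    sum(mT %in% idx & predType[mP] == k) / length(idx)
  }, numeric(1L))
  confusion <- table(truth = kind[mT], pred = predType[mP])
  list(precision = length(mP) / length(pred),
       recall = recall,
       kind_accuracy = if (length(mT)) mean(kind[mT] == predType[mP])
       else NA_real_,
       confusion = confusion, n_pred = length(pred),
       n_truth = length(truth),
       matches = data.frame(truth_idx = mT, pred_idx = mP,
                            overlap = mOv))
}

#' Genome-scale regression harness
#'
#' Re-runs the genome-wide scan on a user-supplied assembly (genome FASTA
#' plus GFF3 annotation) with the full-genome settings (minimum element
#' length 10 nt, upstream-gene distance bound 6,200 nt) and reports the
#' headline quantities of such a run: totals per class, the element
#' length range, the fraction of 10--30-nt elements, the group-1/group-2
#' split, and the per-100-kb window densities.
#'
#' @param fasta,gff paths to the assembly files.
#' @param maxGeneDistance upstream-gene distance bound (nt).
#' @return a list with the run result (\code{result}) and the headline
#'   numbers (\code{stats}).
#' @export
regressionCheck <- function(fasta, gff, maxGeneDistance = 6200L) {
  cfg <- scanConfig(maxGeneDistance = maxGeneDistance)
  res <- runPipeline(fasta, gff, cfg)
  cands <- candidates(res)
  s <- scanSummary(res)
  w <- width(cands)
  type <- mcols(cands)$type
  frac1030 <- function(sel) if (any(sel))
    mean(w[sel] >= 10 & w[sel] <= 30) else NA_real_
  list(result = res,
       stats = list(
         n_total = s$n_total, n_rep = s$n_rep, n_rit = s$n_rit,
         rep_length_range = if (s$n_rep) range(w[type == "REP"]) else NA,
         rit_length_range = if (s$n_rit) range(w[type == "RIT"]) else NA,
         rep_frac_10_30 = frac1030(type == "REP"),
         rit_frac_10_30 = frac1030(type == "RIT"),
         group1 = s$group1, group2 = s$group2,
         density = s$density))
}
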