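#' @importFrom Biostrings DNAStringSet DNAString BStringSet readBStringSet
#'   reverseComplement writeXStringSet subseq
#' @importFrom GenomicRanges GRanges start end width strand seqnames
#' @importFrom IRanges IRanges
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels Seqinfo
NULL

# base-pair classification used throughout the scanner: Watson-Crick plus
# G.T wobble are pairing; everything else (incl. N) is not
.VALID_PAIRS <- c("CG", "GC", "AT", "TA", "GT", "TG")

.isPair <- function(a, b) paste0(a, b) %in% .VALID_PAIRS

.pairClass <- function(a, b) {
  key <- paste0(a, b)
  if (key %in% c("CG", "GC")) "GC"
  else if (key %in% c("AT", "TA")) "AT"
  else if (key %in% c("GT", "TG")) "GT"
  else "MISMATCH"
}

# vectorised reverse complement for plain character vectors over ACGTN
.revcompChar <- function(x) {
  if (!length(x)) return(character())
  as.character(reverseComplement(DNAStringSet(x)))
}

.checkDNA <- function(s, what = "sequence") {
  if (length(s) != 1L || is.na(s))
    stop(what, " must be a single string", call. = FALSE)
  if (grepl("[^ACGTN]", s))
    stop(what, " contains characters outside {A,C,G,T,N}", call. = FALSE)
  invisible(s)
}

#' Reverse complement of a DNA string
#'
#' @param s a DNA string over \code{A,C,G,T,N}.
#' @return the reverse complement; \code{N} maps to \code{N}.
#' @examples
#' revComp("ACGT")  # palindromic: returns "ACGT"
#' revComp("AAA")
#' @export
revComp <- function(s) {
  .checkDNA(s)
  .revcompChar(s)
}

#' Read a genome FASTA file
#'
#' Reads a (possibly multi-record) nucleotide FASTA.  Sequences are
#' uppercased, \code{U} is mapped to \code{T}, and any remaining character
#' outside \code{A,C,G,T} (ambiguity codes and the like) becomes \code{N}.
#' Record names are truncated at the first whitespace, NCBI-style.
#'
#' @param path path to a FASTA file.
#' @return a named \code{DNAStringSet}, one element per record, input order
#'   preserved.
#' @export
readGenome <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  raw <- tryCatch(readBStringSet(path), error = function(e)
    stop("malformed FASTA '", path, "': ", conditionMessage(e),
         call. = FALSE))
  if (length(raw) == 0L) stop("no records in FASTA file: ", path)
  seqs <- toupper(as.character(raw))
  seqs <- chartr("U", "T", seqs)
  seqs <- gsub("[^ACGT]", "N", seqs)
  out <- DNAStringSet(seqs)
  names(out) <- sub("\\s.*$", "", names(raw))
  out
}

#' Read gene features from a GFF3 file
#'
#' Parses a 9-column GFF3 file, keeping only rows whose type (column 3) is
#' in \code{featureClasses}.  Coordinates are returned in the native GFF
#' 1-based inclusive convention as a \code{GRanges}.  The gene identifier
#' is taken from the \code{ID=} attribute, falling back to
#' \code{locus_tag=} and then to a synthetic \code{feat<N>} label.
#'
#' @param path path to a GFF3 file.
#' @param featureClasses character vector of feature types to keep
#'   (default \code{"gene"}).
#' @return a \code{GRanges} with metadata columns \code{gene_id} and
#'   \code{type}; malformed rows (wrong column count, end < start, unknown
#'   strand) raise an error naming the line number.
#' @export
readAnnotation <- function(path, featureClasses = "gene") {
  if (!file.exists(path)) stop("GFF file not found: ", path)
  stopifnot(length(featureClasses) >= 1L)
  lines <- readLines(path, warn = FALSE)
  fasta <- grep("^##FASTA", lines)
  if (length(fasta)) lines <- lines[seq_len(fasta[1L] - 1L)]
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lnum <- which(keep)
  lines <- lines[keep]
  if (!length(lines))
    return(GRanges(gene_id = character(), type = character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L))
    stop("GFF parse error at line ", lnum[which(nf != 9L)[1L]],
         ": expected 9 tab-separated columns, found ",
         nf[which(nf != 9L)[1L]])
  m <- do.call(rbind, fields)
  sel <- m[, 3L] %in% featureClasses
  m <- m[sel, , drop = FALSE]
  lnum <- lnum[sel]
  if (!nrow(m))
    return(GRanges(gene_id = character(), type = character()))
  starts <- suppressWarnings(as.integer(m[, 4L]))
  ends <- suppressWarnings(as.integer(m[, 5L]))
  bad <- which(is.na(starts) | is.na(ends) | ends < starts)
  if (length(bad))
    stop("GFF parse error at line ", lnum[bad[1L]],
         ": invalid coordinates '", m[bad[1L], 4L], "'..'",
         m[bad[1L], 5L], "'")
  badStrand <- which(!m[, 7L] %in% c("+", "-"))
  if (length(badStrand))
    stop("GFF parse error at line ", lnum[badStrand[1L]],
         ": unknown strand '", m[badStrand[1L], 7L], "'")
  ids <- vapply(seq_len(nrow(m)), function(i) {
    attr <- m[i, 9L]
    hit <- regmatches(attr, regexec("(?:^|;)ID=([^;]+)", attr))[[1L]]
    if (length(hit) == 2L) return(hit[2L])
    hit <- regmatches(attr, regexec("(?:^|;)locus_tag=([^;]+)", attr))[[1L]]
    if (length(hit) == 2L) return(hit[2L])
    paste0("feat", i)
  }, character(1L))
  GRanges(m[, 1L], IRanges(starts, ends), strand = m[, 7L],
          gene_id = ids, type = m[, 3L])
}

#' Write candidate outputs as TSV, BED and FASTA
#'
#' Writes the three standard output files for a candidate set:
#' \code{<prefix>.tsv} (1-based inclusive coordinates, full annotation),
#' \code{<prefix>.bed} (BED6, 0-based half-open, score =
#' \code{round(-10 * hairpin_energy)} clamped to [0, 1000]) and
#' \code{<prefix>.fasta} (headers
#' \code{<seq_id>:<start>-<end>(<strand>)|<type>}).  Rows are sorted by
#' (seq_id, start, end).
#'
#' @param cands a candidate \code{GRanges} as produced by
#'   \code{\link{scanGenome}}.
#' @param prefix output path prefix.
#' @return invisibly, the three file paths written.
#' @export
writeOutputs <- function(cands, prefix) {
  dir <- dirname(prefix)
  if (!dir.exists(dir))
    stop("unwritable output prefix: directory '", dir, "' does not exist")
  paths <- paste0(prefix, c(".tsv", ".bed", ".fasta"))
  names(paths) <- c("tsv", "bed", "fasta")
  cands <- sortCandidates(cands)
  df <- candidateTable(cands)
  utils::write.table(df, paths["tsv"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (length(cands) == 0L) {
    file.create(paths["bed"])
    file.create(paths["fasta"])
    return(invisible(paths))
  }
  type <- mcols(cands)$type
  ord <- stats::ave(seq_along(type), type, FUN = seq_along)
  bed <- GRanges(seqnames(cands), IRanges(start(cands), end(cands)),
                 strand = strand(cands),
                 name = paste0(type, "_", ord),
                 score = pmin(pmax(
                   round(-10 * mcols(cands)$hairpin_energy), 0), 1000))
  rtracklayer::export(bed, paths["bed"], format = "bed")
  fa <- DNAStringSet(mcols(cands)$sequence)
  names(fa) <- sprintf("%s:%d-%d(%s)|%s", seqnames(cands), start(cands),
                       end(cands), strand(cands), type)
  writeXStringSet(fa, paths["fasta"])
  invisible(paths)
}

#' Candidate GRanges as a plain data frame (TSV layout)
#'
#' @param cands a candidate \code{GRanges}.
#' @return a \code{data.frame} with the TSV column layout, 1-based
#'   inclusive coordinates.
#' @export
candidateTable <- function(cands) {
  mc <- mcols(cands)
  data.frame(
    seq_id = as.character(seqnames(cands)),
    start = start(cands), end = end(cands),
    strand = as.character(strand(cands)),
    type = mc$type, length = width(cands), sequence = mc$sequence,
    stem_len = mc$stem_len, loop_len = mc$loop_len,
    hairpin_energy = mc$hairpin_energy, tail_score = mc$tail_score,
    upstream_gene = mc$upstream_gene, dist_upstream = mc$dist_upstream,
    downstream_gene = mc$downstream_gene,
    dist_downstream = mc$dist_downstream,
    within_15nt_of_stop = mc$within_15nt_of_stop,
    stringsAsFactors = FALSE)
}

#' Read a candidate TSV back into a GRanges
#'
#' Inverse of the TSV writer in \code{\link{writeOutputs}}; used by the
#' command-line \code{summary} mode to re-derive run summaries.
#'
#' @param path path to a candidate TSV.
#' @return a candidate \code{GRanges}.
#' @export
readCandidates <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  gr <- GRanges(df$seq_id, IRanges(df$start, df$end), strand = df$strand)
  mcols(gr) <- df[, setdiff(colnames(df),
                            c("seq_id", "start", "end", "strand", "length"))]
  gr
}

#' Deterministic candidate ordering
#'
#' Sorts candidates by (seq_id, start, end, strand), the total order used
#' by every writer.
#'
#' @param cands a candidate \code{GRanges}.
#' @return the sorted \code{GRanges}.
#' @export
sortCandidates <- function(cands) {
  if (length(cands) == 0L) return(cands)
  ord <- order(as.character(seqnames(cands)), start(cands), end(cands),
               as.character(strand(cands)))
  cands[ord]
}
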