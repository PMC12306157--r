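#' Extract maximal intergenic regions
#'
#' Projects gene features from both strands onto the forward axis, merges
#' overlapping or adjacent gene intervals, and returns the complement
#' within each sequence record as maximal intergenic regions.  Regions
#' shorter than \code{minLen} are dropped.  Each region carries references
#' to its nearest flanking genes (absent at record edges).
#'
#' @param genes a \code{GRanges} of gene features with a \code{gene_id}
#'   metadata column (see \code{\link{readAnnotation}}).
#' @param genome a named \code{DNAStringSet} (or a named integer vector of
#'   sequence lengths).
#' @param minLen minimum region length kept (nt, default 10 -- the
#'   minimum length of a scorable palindromic element).
#' @return a \code{GRanges} of intergenic regions with metadata columns
#'   \code{left_gene} and \code{right_gene} (\code{NA} at edges), sorted
#'   and pairwise disjoint within each record.
#' @examples
#' genes <- GenomicRanges::GRanges("c1",
#'   IRanges::IRanges(c(101, 501), c(200, 600)),
#'   strand = "+", gene_id = c("g1", "g2"))
#' gen <- Biostrings::DNAStringSet(c(c1 = paste(rep("A", 1000),
#'   collapse = "")))
#' extractIntergenic(genes, gen)
#' @export
extractIntergenic <- function(genes, genome, minLen = 10L) {
  stopifnot(minLen >= 1L)
  lens <- if (is(genome, "DNAStringSet")) {
    stats::setNames(width(genome), names(genome))
  } else {
    stopifnot(!is.null(names(genome)))
    genome
  }
  out <- list()
  for (sid in names(lens)) {
    L <- unname(lens[[sid]])
    g <- genes[as.character(seqnames(genes)) == sid]
    if (length(g)) {
      if (min(start(g)) < 1L || max(end(g)) > L)
        stop("gene outside genome bounds on '", sid, "'")
    }
    cov <- GenomicRanges::reduce(g, ignore.strand = TRUE)
    cov <- cov[order(start(cov))]
    # complement of the merged gene cover within [1, L]
    starts <- c(1L, end(cov) + 1L)
    ends <- c(start(cov) - 1L, L)
    keep <- ends >= starts
    if (!any(keep)) next
    reg <- GRanges(rep(sid, sum(keep)), IRanges(starts[keep], ends[keep]))
    gid <- mcols(g)$gene_id
    ge <- end(g); gs <- start(g)
    leftIdx <- vapply(start(reg), function(s) {
      cand <- which(ge <= s - 1L)
      if (!length(cand)) NA_integer_ else cand[which.max(ge[cand])]
    }, integer(1L))
    rightIdx <- vapply(end(reg), function(e) {
      cand <- which(gs >= e + 1L)
      if (!length(cand)) NA_integer_ else cand[which.min(gs[cand])]
    }, integer(1L))
    mcols(reg)$left_gene <- ifelse(is.na(leftIdx), NA_character_,
                                   gid[leftIdx])
    mcols(reg)$right_gene <- ifelse(is.na(rightIdx), NA_character_,
                                    gid[rightIdx])
    out[[sid]] <- reg[width(reg) >= minLen]
  }
  if (!length(out))
    return(GRanges(left_gene = character(), right_gene = character()))
  res <- do.call(c, unname(out))
  names(res) <- NULL
  res
}
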