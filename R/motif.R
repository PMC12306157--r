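#' Motif-group similarity score
#'
#' Similarity between two motif groups given the number of unique motifs
#' in each (\code{na}, \code{nb}) and the number of motifs found similar
#' between them (\code{nab}): \code{nab / (na + nb)}.  The score lies in
#' [0, 0.5]; 0.5 is full overlap of two equally sized groups.
#'
#' @param na,nb number of unique motifs in group A and group B (>= 1).
#' @param nab number of similar motifs identified between the groups.
#' @return the similarity score.
#' @examples
#' similarityScore(10, 6, 4)  # 0.25
#' @export
similarityScore <- function(na, nb, nab) {
  if (na < 1L || nb < 1L) stop("na and nb must be >= 1")
  if (nab < 0L || nab > min(na, nb))
    stop("nab must lie in [0, min(na, nb)]")
  nab / (na + nb)
}

#' Pairwise motif-group similarity matrix
#'
#' Builds the symmetric similarity matrix and per-group totals of
#' significant matches from a table of pairwise comparisons, e.g. the
#' tally of significant motif matches an external motif-comparison tool
#' reports between groups.
#'
#' @param pairs a \code{data.frame} with columns \code{group_a, group_b,
#'   na, nb, nab}, one row per unordered group pair (a duplicated pair
#'   with inconsistent counts is an error).
#' @return a list with \code{scores} (symmetric matrix; diagonal 0.5 by
#'   convention) and \code{totals} (per-group sum of \code{nab} over all
#'   partners, diagonal excluded), groups in input order.
#' @export
similarityMatrix <- function(pairs) {
  need <- c("group_a", "group_b", "na", "nb", "nab")
  if (!all(need %in% colnames(pairs)))
    stop("pairs must have columns: ", paste(need, collapse = ", "))
  groups <- unique(c(rbind(pairs$group_a, pairs$group_b)))
  sizes <- stats::setNames(rep(NA_integer_, length(groups)), groups)
  m <- matrix(NA_real_, length(groups), length(groups),
              dimnames = list(groups, groups))
  tot <- stats::setNames(numeric(length(groups)), groups)
  diag(m) <- 0.5
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$group_a[i]; b <- pairs$group_b[i]
    for (gn in c(a, b)) {
      sz <- if (gn == a) pairs$na[i] else pairs$nb[i]
      if (!is.na(sizes[gn]) && sizes[gn] != sz)
        stop("inconsistent motif count for group '", gn, "'")
      sizes[gn] <- sz
    }
    sc <- similarityScore(pairs$na[i], pairs$nb[i], pairs$nab[i])
    if (a == b) next
    if (!is.na(m[a, b]) && m[a, b] != sc)
      stop("asymmetric input: conflicting entries for pair ",
           a, " / ", b)
    m[a, b] <- sc; m[b, a] <- sc
    tot[a] <- tot[a] + pairs$nab[i]
    tot[b] <- tot[b] + pairs$nab[i]
  }
  m[is.na(m)] <- 0
  list(scores = m, totals = tot)
}

#' Read a motif comparison pair table
#'
#' Reads a TSV with columns \code{group_a, group_b, na, nb, nab} (the
#' output shape of an external motif comparison run).
#'
#' @param path path to the TSV.
#' @return a \code{data.frame} suitable for
#'   \code{\link{similarityMatrix}}.
#' @export
readMotifPairs <- function(path) {
  if (!file.exists(path)) stop("pair table not found: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
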