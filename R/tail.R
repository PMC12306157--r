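#' Thymine-tail score
#'
#' Scores the up-to-\code{window}-length sequence immediately 3' of a
#' hairpin for thymine richness:
#' \deqn{score = -\sum_{i=1}^{L} \prod_{j=1}^{i} w(x_j)}
#' with \eqn{w(T) = wT} and \eqn{w(other) = wOther}, truncated at the
#' available tail length.  More negative scores indicate more T-rich
#' tails; the cumulative product makes thymines nearest the hairpin count
#' most.
#'
#' @param tail DNA string immediately 3' of the hairpin on the element's
#'   strand (may be shorter than the window at region edges; may be
#'   empty).
#' @param model a \code{\link{tailModel}}.
#' @return the tail score (0 for an empty tail).
#' @examples
#' tailScore(strrep("T", 15))  # about -7.147
#' tailScore(strrep("A", 15))  # about -1.500
#' @export
tailScore <- function(tail, model = tailModel()) {
  if (!nchar(tail)) return(0)
  .checkDNA(tail, "tail")
  chars <- strsplit(tail, "", fixed = TRUE)[[1L]]
  chars <- chars[seq_len(min(model@window, length(chars)))]
  w <- ifelse(chars == "T", model@wT, model@wOther)
  -sum(cumprod(w))
}

#' Classify an element as RIT or REP
#'
#' An element whose tail score is at or below the tail cutoff is a
#' Rho-independent terminator (RIT); every other surviving element is a
#' putative repetitive extragenic palindrome (REP).  The classification
#' is total: each element receives exactly one label.
#'
#' @param tail DNA string immediately 3' of the hairpin (see
#'   \code{\link{tailScore}}).
#' @param model a \code{\link{tailModel}}.
#' @return \code{"RIT"} or \code{"REP"}.
#' @examples
#' classifyElement(strrep("T", 15))  # "RIT"
#' classifyElement(strrep("A", 15))  # "REP"
#' @export
classifyElement <- function(tail, model = tailModel()) {
  if (tailScore(tail, model) <= model@tailCutoff) "RIT" else "REP"
}
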