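# shared fixture builders (everything is generated in code; no stored data)

writeTempFasta <- function(text) {
  path <- tempfile(fileext = ".fasta")
  writeLines(text, path)
  path
}

writeTempGff <- function(rows) {
  path <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", rows), path)
  path
}

# independent reverse complement: chartr + explicit reversal, no Biostrings
oracleRevcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1L]]),
        collapse = "")
}

# brute-force seed-pair oracle: all (i, j) with revcomp k-mer identity,
# non-overlapping arms and span within the threshold
oracleSeedPairs <- function(s, k = 6L, maxSpan = 50L) {
  L <- nchar(s)
  if (L < 2L * k) return(data.frame(i = integer(), j = integer()))
  starts <- seq_len(L - k + 1L)
  kmers <- substring(s, starts, starts + k - 1L)
  res <- list()
  for (i in starts) {
    if (grepl("N", kmers[i], fixed = TRUE)) next
    rc <- oracleRevcomp(kmers[i])
    js <- starts[starts >= i + k & starts + k - 1L <= i + maxSpan - 1L]
    js <- js[kmers[js] == rc & !grepl("N", kmers[js], fixed = TRUE)]
    if (length(js)) res[[length(res) + 1L]] <- data.frame(i = i, j = js)
  }
  if (!length(res)) return(data.frame(i = integer(), j = integer()))
  out <- do.call(rbind, res)
  out[order(out$i, out$j), , drop = FALSE]
}

randomSeq <- function(L, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# build an annotated candidate GRanges from a compact spec data.frame
makeCandidates <- function(df, seqlens = NULL) {
  defaults <- list(strand = "+", type = "REP", sequence = NA_character_,
                   stem_len = 5L, loop_len = 4L, hairpin_energy = -7.2,
                   tail_score = -1.0, upstream_gene = NA_character_,
                   dist_upstream = NA_integer_,
                   downstream_gene = NA_character_,
                   dist_downstream = NA_integer_,
                   dist_stop = NA_integer_,
                   within_15nt_of_stop = FALSE)
  for (nm in names(defaults))
    if (is.null(df[[nm]])) df[[nm]] <- rep(defaults[[nm]], nrow(df))
  if (all(is.na(df$sequence)))
    df$sequence <- vapply(df$end - df$start + 1L, function(n)
      randomSeq(n), character(1L))
  gr <- GenomicRanges::GRanges(df$seq_id,
                               IRanges::IRanges(df$start, df$end),
                               strand = df$strand)
  if (!is.null(seqlens))
    GenomeInfoDb::seqlengths(gr) <- seqlens[GenomeInfoDb::seqlevels(gr)]
  S4Vectors::mcols(gr) <- df[, c("type", "sequence", "stem_len",
                                 "loop_len", "hairpin_energy",
                                 "tail_score", "upstream_gene",
                                 "dist_upstream", "downstream_gene",
                                 "dist_downstream", "dist_stop",
                                 "within_15nt_of_stop")]
  gr
}

# the standard clean fixture: 20 REPs (incl. the group-1/2 boundary pair)
# and 10 RITs on both strands in a 100-kb background
cleanImplantSpecs <- function() {
  rbind(implantSpec("REP", n = 15),
        implantSpec("REP", n = 1, stopGap = 15L),
        implantSpec("REP", n = 1, stopGap = 16L),
        implantSpec("REP", n = 3, strand = "-"),
        implantSpec("RIT", n = 5),
        implantSpec("RIT", n = 5, strand = "-"))
}

buildCleanFixture <- function(genomeSeed, implantSeed, length = 100000L) {
  bg <- makeGenome(length, gc = 0.5, seed = genomeSeed)
  implantElements(bg, cleanImplantSpecs(), seed = implantSeed)
}

# small, fast variant for unit tests
buildSmallFixture <- function(seed = 7L) {
  bg <- makeGenome(20000L, gc = 0.5, seed = seed)
  specs <- rbind(implantSpec("REP", n = 3),
                 implantSpec("RIT", n = 2),
                 implantSpec("RIT", n = 1, strand = "-"))
  implantElements(bg, specs, seed = seed + 1L)
}
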