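mkGenes <- function(starts, ends, strand = "+", seq = "c1") {
  GenomicRanges::GRanges(rep(seq, length(starts)),
                         IRanges::IRanges(starts, ends),
                         strand = rep_len(strand, length(starts)),
                         gene_id = paste0("g", seq_along(starts)))
}

mkGenome <- function(L, name = "c1") {
  g <- Biostrings::DNAStringSet(strrep("A", L))
  names(g) <- name
  g
}

test_that("intergenic regions are the complement of the gene cover", {
  reg <- extractIntergenic(mkGenes(c(101, 501), c(200, 600)),
                           mkGenome(1000), minLen = 1L)
  expect_identical(GenomicRanges::start(reg), c(1L, 201L, 601L))
  expect_identical(GenomicRanges::end(reg), c(100L, 500L, 1000L))
  # flanking references, absent at the record edges
  expect_identical(S4Vectors::mcols(reg)$left_gene,
                   c(NA, "g1", "g2"))
  expect_identical(S4Vectors::mcols(reg)$right_gene,
                   c("g1", "g2", NA))
})

test_that("overlapping and adjacent genes merge into one blocked interval", {
  reg <- extractIntergenic(mkGenes(c(101, 251), c(300, 400),
                                   strand = c("+", "-")),
                           mkGenome(1000), minLen = 1L)
  expect_identical(GenomicRanges::start(reg), c(1L, 401L))
  expect_identical(GenomicRanges::end(reg), c(100L, 1000L))
})

test_that("degenerate gene sets are handled", {
  reg <- extractIntergenic(mkGenes(integer(), integer()),
                           mkGenome(500), minLen = 1L)
  expect_identical(GenomicRanges::start(reg), 1L)
  expect_identical(GenomicRanges::end(reg), 500L)
  expect_error(extractIntergenic(mkGenes(400, 600), mkGenome(500)),
               "outside genome bounds")
})

test_that("regions shorter than minLen are dropped", {
  reg <- extractIntergenic(mkGenes(c(11, 25), c(20, 40)),
                           mkGenome(100), minLen = 10L)
  expect_identical(GenomicRanges::start(reg), c(1L, 41L))
  reg <- extractIntergenic(mkGenes(c(11, 25), c(20, 40)),
                           mkGenome(100), minLen = 4L)
  expect_identical(GenomicRanges::start(reg), c(1L, 21L, 41L))
})

test_that("region lengths and gene cover conserve the genome length", {
  set.seed(23)
  for (rep in 1:25) {
    L <- sample(200:2000, 1)
    n <- sample(1:8, 1)
    s <- sort(sample(seq_len(L - 20L), n))
    e <- pmin(s + sample(5:200, n, replace = TRUE), L)
    genes <- mkGenes(s, e, strand = sample(c("+", "-"), n, TRUE))
    reg <- extractIntergenic(genes, mkGenome(L), minLen = 1L)
    cover <- GenomicRanges::reduce(genes, ignore.strand = TRUE)
    expect_identical(sum(GenomicRanges::width(reg)) +
                       sum(GenomicRanges::width(cover)), L)
    # brute force: no region position is covered by any gene
    covered <- logical(L)
    for (i in seq_along(genes)) covered[s[i]:e[i]] <- TRUE
    for (i in seq_along(reg)) {
      expect_false(any(covered[GenomicRanges::start(reg)[i]:
                                 GenomicRanges::end(reg)[i]]))
    }
  }
})
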