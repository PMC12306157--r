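test_that("background genomes are reproducible with the requested GC", {
  g1 <- makeGenome(10000, gc = 0.5, seed = 7)
  g2 <- makeGenome(10000, gc = 0.5, seed = 7)
  expect_identical(as.character(g1), as.character(g2))
  g3 <- makeGenome(100000, gc = 0.7, seed = 7)
  f <- Biostrings::letterFrequency(g3[[1]], "GC", as.prob = TRUE)
  expect_lt(abs(f - 0.7), 0.02)
  g0 <- makeGenome(1000, gc = 0, seed = 7)
  expect_identical(
    unname(Biostrings::letterFrequency(g0[[1]], "GC"))[1], 0L)
})

test_that("implanting produces consistent truth, genes and files", {
  bg <- makeGenome(20000, 0.5, seed = 61)
  specs <- rbind(implantSpec("REP", n = 3),
                 implantSpec("RIT", n = 2, strand = c("+", "-")))
  prefix <- file.path(tempdir(), "fx")
  fx <- implantElements(bg, specs, seed = 62, outPrefix = prefix)
  expect_length(fx$truth, 5L)
  expect_identical(sum(S4Vectors::mcols(fx$truth)$kind == "REP"), 3L)
  expect_identical(sum(S4Vectors::mcols(fx$truth)$kind == "RIT"), 2L)
  expect_length(fx$genes, 6L)        # one anchor gene per implant + 1
  # determinism: identical inputs give identical genomes and truth
  fx2 <- implantElements(bg, specs, seed = 62)
  expect_identical(as.character(fx$genome), as.character(fx2$genome))
  expect_identical(fx$truth, fx2$truth)
  # written files round-trip
  expect_identical(as.character(readGenome(fx$paths["fasta"])),
                   as.character(fx$genome))
  genesBack <- readAnnotation(fx$paths["gff"])
  expect_identical(GenomicRanges::start(genesBack),
                   GenomicRanges::start(fx$genes))
  expect_identical(S4Vectors::mcols(genesBack)$gene_id,
                   S4Vectors::mcols(fx$genes)$gene_id)
  truthBack <- rtracklayer::import(fx$paths["bed"])
  expect_identical(GenomicRanges::start(truthBack),
                   GenomicRanges::start(fx$truth))
  expect_identical(S4Vectors::mcols(truthBack)$name,
                   S4Vectors::mcols(fx$truth)$kind)
})

test_that("implants on both strands carry their exact hairpin sequence", {
  bg <- makeGenome(20000, 0.5, seed = 67)
  fx <- implantElements(bg, rbind(implantSpec("REP", armLen = 8L),
                                  implantSpec("REP", strand = "-")),
                        seed = 68)
  for (i in 1:2) {
    hp <- as.character(Biostrings::subseq(
      fx$genome[[1]], GenomicRanges::start(fx$truth)[i],
      GenomicRanges::end(fx$truth)[i]))
    # a perfect palindrome with an all-A loop in element orientation
    elem <- if (as.character(GenomicRanges::strand(fx$truth))[i] == "+")
      hp else revComp(hp)
    arm <- substr(elem, 1, 8)
    expect_identical(substr(elem, 9, 12), "AAAA")
    expect_identical(substr(elem, 13, 20), revComp(arm))
  }
})

test_that("a genome too small for the layout is rejected", {
  bg <- makeGenome(5000, 0.5, seed = 71)
  expect_error(implantElements(bg, implantSpec("REP", n = 10), seed = 72),
               "too short")
})

test_that("recovery evaluation matches by reciprocal overlap", {
  truth <- GenomicRanges::GRanges("c1",
    IRanges::IRanges(c(100, 300, 600), c(119, 319, 619)),
    strand = "+", kind = c("REP", "REP", "RIT"))
  # identical predictions: perfect precision and recall
  pred <- makeCandidates(data.frame(
    seq_id = "c1", start = c(100L, 300L, 600L), end = c(119L, 319L, 619L),
    type = c("REP", "REP", "RIT")))
  ev <- evaluateRecovery(pred, truth)
  expect_identical(ev$precision, 1)
  expect_identical(unname(ev$recall), c(1, 1))
  expect_identical(ev$kind_accuracy, 1)

  # empty predictions: zero recall, undefined precision
  ev0 <- evaluateRecovery(pred[0], truth)
  expect_identical(unname(ev0$recall), c(0, 0))
  expect_true(is.na(ev0$precision))

  # a REP truth called RIT: confusion, not recall
  predX <- makeCandidates(data.frame(
    seq_id = "c1", start = c(100L, 300L, 600L), end = c(119L, 319L, 619L),
    type = c("RIT", "REP", "RIT")))
  evX <- evaluateRecovery(predX, truth)
  expect_identical(unname(evX$recall["REP"]), 0.5)
  expect_identical(evX$confusion["REP", "RIT"], 1L)
  expect_lt(evX$kind_accuracy, 1)

  # sub-threshold overlap does not match
  predY <- makeCandidates(data.frame(
    seq_id = "c1", start = 112L, end = 131L, type = "REP"))
  evY <- evaluateRecovery(predY, truth)
  expect_identical(unname(evY$recall["REP"]), 0)
})
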