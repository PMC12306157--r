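test_that("FASTA reading normalizes case, U and ambiguity codes", {
  p <- writeTempFasta(c(">c1 some description", "acgt"))
  g <- readGenome(p)
  expect_identical(names(g), "c1")
  expect_identical(as.character(g[[1]]), "ACGT")
  expect_identical(Biostrings::width(g), 4L)

  p <- writeTempFasta(c(">c1", "ACGU"))
  expect_identical(as.character(readGenome(p)[[1]]), "ACGT")

  p <- writeTempFasta(c(">c1", "ACRYGT"))
  expect_identical(as.character(readGenome(p)[[1]]), "ACNNGT")

  p <- writeTempFasta(c(">c1", "ACGT", ">c2", "GG", "TT"))
  g <- readGenome(p)
  expect_identical(names(g), c("c1", "c2"))
  expect_identical(as.character(g[[2]]), "GGTT")
})

test_that("FASTA reading rejects degenerate input", {
  p <- tempfile(); file.create(p)
  expect_error(readGenome(p), "no records")
  expect_error(readGenome(tempfile()), "not found")
})

test_that("GFF reading converts, filters and extracts identifiers", {
  p <- writeTempGff(c(
    "c1\t.\tgene\t101\t200\t.\t+\t.\tID=g1;Name=foo",
    "c1\t.\texon\t101\t150\t.\t+\t.\tID=e1",
    "c1\t.\tgene\t301\t400\t.\t-\t.\tlocus_tag=b0001",
    "c1\t.\tgene\t501\t600\t.\t+\t.\tnote=nameless"))
  g <- readAnnotation(p)
  expect_length(g, 3L)                       # exon filtered out
  expect_identical(GenomicRanges::start(g)[1], 101L)
  expect_identical(GenomicRanges::end(g)[1], 200L)
  expect_identical(GenomicRanges::width(g)[1], 100L)
  expect_identical(as.character(GenomicRanges::strand(g)),
                   c("+", "-", "+"))
  expect_identical(S4Vectors::mcols(g)$gene_id[1:2], c("g1", "b0001"))
  expect_match(S4Vectors::mcols(g)$gene_id[3], "^feat")
  # requesting CDS instead
  expect_length(readAnnotation(p, "exon"), 1L)
})

test_that("malformed GFF rows raise errors naming the line", {
  p <- writeTempGff(c("c1\t.\tgene\t101\t200\t.\t+\t.\tID=g1",
                      "c1\tgene\t10\t20"))
  expect_error(readAnnotation(p), "line 3.*9 tab-separated")
  p <- writeTempGff("c1\t.\tgene\t200\t100\t.\t+\t.\tID=g1")
  expect_error(readAnnotation(p), "line 2.*coordinates")
  p <- writeTempGff("c1\t.\tgene\t100\t200\t.\t?\t.\tID=g1")
  expect_error(readAnnotation(p), "line 2.*strand")
})

test_that("reverse complement is correct and involutive", {
  expect_identical(revComp("ACGT"), "ACGT")
  expect_identical(revComp("AAA"), "TTT")
  expect_identical(revComp("ANG"), "CNT")
  expect_error(revComp("ACGX"), "outside")
  set.seed(11)
  for (i in 1:20) {
    s <- randomSeq(sample(1:50, 1))
    expect_identical(revComp(revComp(s)), s)
  }
})

test_that("output writers honour the coordinate conventions", {
  # internal 1-based [100, 120] must print TSV 100..120 and BED 99..120
  cands <- makeCandidates(data.frame(
    seq_id = c("c2", "c1"), start = c(50L, 100L), end = c(70L, 120L),
    type = c("RIT", "REP"), hairpin_energy = c(-5.0, -7.2),
    tail_score = c(-3.0, -1.0)), seqlens = c(c1 = 1000L, c2 = 1000L))
  prefix <- file.path(tempdir(), "outtest")
  writeOutputs(cands, prefix)
  tsv <- read.delim(paste0(prefix, ".tsv"))
  expect_identical(colnames(tsv),
    c("seq_id", "start", "end", "strand", "type", "length", "sequence",
      "stem_len", "loop_len", "hairpin_energy", "tail_score",
      "upstream_gene", "dist_upstream", "downstream_gene",
      "dist_downstream", "within_15nt_of_stop"))
  # sorted by (seq_id, start, end)
  expect_identical(tsv$seq_id, c("c1", "c2"))
  expect_identical(tsv$start[1], 100L)
  expect_identical(tsv$end[1], 120L)
  expect_identical(tsv$length, tsv$end - tsv$start + 1L)
  bed <- read.table(paste0(prefix, ".bed"), sep = "\t")
  expect_identical(bed$V2, c(99L, 49L))
  expect_identical(bed$V3, c(120L, 70L))
  expect_identical(bed$V4, c("REP_1", "RIT_1"))
  expect_identical(bed$V5, c(72L, 50L))  # round(-10 * energy)
  fa <- readGenome(paste0(prefix, ".fasta"))
  expect_identical(names(fa), c("c1:100-120(+)|REP", "c2:50-70(+)|RIT"))
})

test_that("FASTA output round-trips candidate sequences exactly", {
  set.seed(3)
  cands <- makeCandidates(data.frame(
    seq_id = "c1", start = c(10L, 200L, 500L),
    end = c(29L, 219L, 540L)), seqlens = c(c1 = 1000L))
  prefix <- file.path(tempdir(), "rt")
  writeOutputs(cands, prefix)
  fa <- readGenome(paste0(prefix, ".fasta"))
  expect_identical(unname(as.character(fa)),
                   S4Vectors::mcols(sortCandidates(cands))$sequence)
})

test_that("empty candidate sets write header-only/empty files", {
  cands <- makeCandidates(data.frame(seq_id = character(),
                                     start = integer(), end = integer(),
                                     sequence = character()))
  prefix <- file.path(tempdir(), "empty")
  writeOutputs(cands, prefix)
  expect_identical(length(readLines(paste0(prefix, ".tsv"))), 1L)
  expect_identical(file.size(paste0(prefix, ".bed")), 0)
  expect_identical(file.size(paste0(prefix, ".fasta")), 0)
  expect_error(writeOutputs(cands, "/no/such/dir/x"), "unwritable")
})
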