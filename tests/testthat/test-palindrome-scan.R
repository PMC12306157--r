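# the worked 22-nt example used across the scan tests: a GC-rich arm pair
# with a 4-nt loop after inward extension
wseq <- paste0("AA", "GCCGGAT", "TTTT", "ATCCGGC", "AA")

test_that("kmerize enumerates positioned k-mers and excludes N", {
  km <- kmerize("ACGTACG", 6L)
  expect_identical(nrow(km), 2L)
  expect_identical(km$offset, 1:2)
  expect_identical(km$kmer, c("ACGTAC", "CGTACG"))
  expect_identical(nrow(kmerize("ACGTA", 6L)), 0L)
  km <- kmerize("ACGNTAGCA", 4L)
  expect_identical(km$seedable, !grepl("N", km$kmer))
})

test_that("seed pairs match the worked example and the thresholds", {
  seeds <- findSeedPairs(wseq, scanConfig())
  expect_true(any(seeds$ls == 3 & seeds$le == 8 &
                    seeds$rs == 15 & seeds$re == 20))
  # all-A sequences cannot seed (their revcomp k-mer is absent)
  expect_identical(nrow(findSeedPairs(strrep("A", 100), scanConfig())), 0L)
  # a pair beyond the span threshold is excluded
  far <- paste0("GCCGGA", strrep("A", 40), "TCCGGC")   # outer span 52
  expect_identical(nrow(findSeedPairs(far, scanConfig())), 0L)
  expect_identical(nrow(findSeedPairs(far, scanConfig(maxSpan = 60L))), 1L)
  # start-mode measures the start-position difference instead
  expect_identical(nrow(findSeedPairs(far, scanConfig(maxSpan = 50L,
                                                      spanMode = "start"))),
                   1L)
})

test_that("seed detection equals the brute-force oracle", {
  set.seed(31)
  for (i in 1:40) {
    s <- randomSeq(sample(80:400, 1), gc = runif(1, 0.3, 0.7))
    got <- findSeedPairs(s, scanConfig())
    want <- oracleSeedPairs(s)
    expect_identical(got$ls, want$i)
    expect_identical(got$rs, want$j)
  }
})

test_that("extension grows to the maximal pair and respects bounds", {
  p <- extendPair(c(3L, 8L, 15L, 20L), wseq)
  expect_identical(unlist(p[1, 1:4], use.names = FALSE),
                   c(3L, 9L, 14L, 20L))
  # flush against the sequence edge: no outward growth possible
  edge <- paste0("GCCGGA", "TTTT", "TCCGGC")
  p <- extendPair(c(1L, 6L, 11L, 16L), edge)
  expect_identical(unlist(p[1, 1:4], use.names = FALSE),
                   c(1L, 6L, 11L, 16L))
})

test_that("extension is idempotent and arms never cross", {
  set.seed(37)
  for (i in 1:15) {
    s <- randomSeq(300)
    seeds <- findSeedPairs(s, scanConfig())
    for (r in seq_len(min(nrow(seeds), 10L))) {
      e1 <- extendPair(seeds[r, ], s)
      expect_true(e1$le < e1$rs)
      e2 <- extendPair(e1, s)
      expect_identical(e1[, 1:4], e2[, 1:4])
    }
  }
})

test_that("assembly merges across short bulges and records gaps", {
  # two extended arm pairs separated by a 1-nt bulge on each arm
  bseq <- paste0("AA", "GCCGGA", "C", "GCTGAC", "AAAA",
                 "GTCAGC", "T", "TCCGGC", "AA")
  seeds <- findSeedPairs(bseq, scanConfig())
  ext <- do.call(rbind, lapply(seq_len(nrow(seeds)), function(i)
    extendPair(seeds[i, ], bseq)))
  merged <- assemblePairs(ext, scanConfig())
  hit <- merged[merged$ls == 3 & merged$re == 32, ]
  expect_identical(nrow(hit), 1L)
  expect_identical(unlist(hit[1, 1:4], use.names = FALSE),
                   c(3L, 15L, 20L, 32L))
  expect_identical(hit$gapL[[1]], 9L)
  expect_identical(hit$gapR[[1]], 26L)
  # the merged stem prices both bulges with the gap penalty
  h <- scoreHairpin(inferStructure(hit, bseq))
  expect_identical(sum(h@stem == "GAP"), 2L)
  expect_equal(h@energy, 9 * -2.3 + 3 * -0.9 + 2 * 6.0 + (4 - 2))
})

test_that("assembly respects the gap threshold and deduplicates", {
  # bulges of 3 nt exceed the default maximum gap of 2
  bseq <- paste0("AA", "GCCGGA", "CAC", "GCTGAC", "AAAA",
                 "GTCAGC", "TCT", "TCCGGC", "AA")
  seeds <- findSeedPairs(bseq, scanConfig())
  ext <- do.call(rbind, lapply(seq_len(nrow(seeds)), function(i)
    extendPair(seeds[i, ], bseq)))
  merged <- assemblePairs(ext, scanConfig())
  expect_false(any(merged$ls == 3 & merged$le == 17 &
                     merged$rs == 22 & merged$re == 36))
  wide <- assemblePairs(ext, scanConfig(maxGap = 3L))
  expect_true(any(wide$ls == 3 & wide$le == 17 &
                    wide$rs == 22 & wide$re == 36))
  # duplicate pairs collapse to one
  dup <- rbind(ext[1, ], ext[1, ])
  expect_identical(nrow(assemblePairs(dup, scanConfig())), 1L)
})
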