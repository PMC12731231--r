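test_that("k-mer index bounds, degenerate inputs and shared-reference sets behave", {
  set.seed(31)
  s <- randomDNA(100)
  idx1 <- kmerIndex(Biostrings::DNAStringSet(s), k = 21)
  expect_lte(length(idx1@kmers), 2 * (100 - 21 + 1))
  # identical references add nothing
  idx2 <- kmerIndex(Biostrings::DNAStringSet(c(s, s)), k = 21)
  expect_identical(idx1@kmers, idx2@kmers)
  expect_error(kmerIndex(Biostrings::DNAStringSet("ACGTACGT"), k = 21),
               "unusable index")
  expect_error(kmerIndex(Biostrings::DNAStringSet(s), k = 4))
})

test_that("reads match by exact containment, either strand, and tolerate a central substitution", {
  set.seed(32)
  ref <- randomDNA(300)
  idx <- kmerIndex(Biostrings::DNAStringSet(ref), k = 21)
  read <- substr(ref, 50, 99)                      # exact 50-mer
  expect_true(readMatches(read, idx))
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(read)))
  expect_true(readMatches(rc, idx))                # reverse strand
  # one substitution at position 25 of 50 leaves a clean >=21-base flank
  ch <- strsplit(read, "")[[1]]
  ch[25] <- setdiff(c("A", "C", "G", "T"), ch[25])[1]
  expect_true(readMatches(paste(ch, collapse = ""), idx))
  # random reads share no 21-mer (checked, then asserted)
  rnd <- replicate(20, randomDNA(50))
  expect_false(any(readMatches(rnd, idx)))
  expect_false(readMatches("ACGT", idx))           # shorter than k
})

test_that("filterPairs keeps pairs with >=1 matching mate, rescues the partner, drops the rest", {
  set.seed(33)
  ref <- randomDNA(500)
  idx <- kmerIndex(Biostrings::DNAStringSet(ref), k = 21)
  # pair 1: both mates from reference; pair 2: R1 only; pair 3: neither
  r1seqs <- c(substr(ref, 1, 100), substr(ref, 101, 200), randomDNA(100))
  r2seqs <- c(substr(ref, 201, 300), randomDNA(100), randomDNA(100))
  stopifnot(!any(readMatches(c(r1seqs[3], r2seqs[2:3]), idx)))
  r1 <- writeFastqRecords(paste0("p", 1:3, "/1"), r1seqs, tempfile())
  r2 <- writeFastqRecords(paste0("p", 1:3, "/2"), r2seqs, tempfile())
  o1 <- tempfile(); o2 <- tempfile()
  fs <- filterPairs(r1, r2, idx, o1, o2)
  n <- filterCounts(fs)
  expect_equal(unname(n[c("inputPairs", "bothMatched", "r1Only", "r2Only",
                          "rescuedMates", "outputPairs")]),
               c(3, 1, 1, 0, 1, 2))
  out1 <- readLines(o1); out2 <- readLines(o2)
  expect_equal(out1[c(1, 5)], c("@p1/1", "@p2/1"))
  # rescued mate emitted verbatim from input
  expect_equal(out2[6], r2seqs[2])
  expect_equal(length(out1), 8L)
})

test_that("output records are byte-identical to input and filtering is idempotent", {
  set.seed(34)
  ref <- randomDNA(600)
  idx <- kmerIndex(Biostrings::DNAStringSet(ref), k = 21)
  names <- paste0("r", 1:4)
  r1seqs <- c(substr(ref, 1, 80), substr(ref, 81, 160), randomDNA(80),
              substr(ref, 161, 240))
  r2seqs <- c(substr(ref, 241, 320), randomDNA(80), randomDNA(80),
              substr(ref, 321, 400))
  r1 <- writeFastqRecords(paste0(names, "/1"), r1seqs, tempfile())
  r2 <- writeFastqRecords(paste0(names, "/2"), r2seqs, tempfile())
  o1 <- tempfile(); o2 <- tempfile()
  filterPairs(r1, r2, idx, o1, o2)
  inRecs <- matrix(readLines(r1), nrow = 4)
  outRecs <- matrix(readLines(o1), nrow = 4)
  expect_true(all(apply(outRecs, 2, paste, collapse = "\n") %in%
                  apply(inRecs, 2, paste, collapse = "\n")))
  # re-filtering the filtered output changes nothing
  oo1 <- tempfile(); oo2 <- tempfile()
  fs2 <- filterPairs(o1, o2, idx, oo1, oo2)
  expect_equal(filterCounts(fs2)[["outputPairs"]],
               filterCounts(fs2)[["inputPairs"]])
  expect_identical(readLines(oo1), readLines(o1))
  expect_identical(readLines(oo2), readLines(o2))
})

test_that("pairing errors are reported with the offending record; empty input gives a zeroed summary", {
  idx <- kmerIndex(Biostrings::DNAStringSet(randomDNA(100)), k = 21)
  a <- writeFastqRecords(c("x/1", "y/1"), c(randomDNA(30), randomDNA(30)),
                         tempfile())
  b <- writeFastqRecords(c("x/2", "z/2"), c(randomDNA(30), randomDNA(30)),
                         tempfile())
  expect_error(filterPairs(a, b, idx, tempfile(), tempfile()),
               "pairing error.*record 2")
  short <- writeFastqRecords("x/2", randomDNA(30), tempfile())
  expect_error(filterPairs(a, short, idx, tempfile(), tempfile()),
               "pairing error")
  e1 <- tempfile(); file.create(e1)
  e2 <- tempfile(); file.create(e2)
  fs <- filterPairs(e1, e2, idx, tempfile(), tempfile())
  expect_equal(filterCounts(fs)[["inputPairs"]], 0)
  expect_equal(filterCounts(fs)[["outputPairs"]], 0)
})

test_that("nine-locus-filtered reads are a subset of all-locus-filtered reads", {
  db <- makeTestReference(genes = c("A", "B", "DRB1", "E", "MICA"),
                          allelesPerGene = 2L, len = 300L, seed = 35)
  nine <- restrictToGenes(db, intersect(refGenes(db), nineClassicalGenes()))
  set.seed(36)
  seqs <- as.character(refSequences(db))
  r1seqs <- c(vapply(seqs, function(s) substr(s, 1, 80), character(1)),
              replicate(5, randomDNA(80)))
  r2seqs <- c(vapply(seqs, function(s) substr(s, 101, 180), character(1)),
              replicate(5, randomDNA(80)))
  nm <- paste0("q", seq_along(r1seqs))
  r1 <- writeFastqRecords(paste0(nm, "/1"), r1seqs, tempfile())
  r2 <- writeFastqRecords(paste0(nm, "/2"), r2seqs, tempfile())
  allOut <- c(tempfile(), tempfile()); nineOut <- c(tempfile(), tempfile())
  filterPairs(r1, r2, kmerIndex(db), allOut[1], allOut[2])
  filterPairs(r1, r2, kmerIndex(nine), nineOut[1], nineOut[2])
  idsOf <- function(p) grep("^@", readLines(p), value = TRUE)
  expect_true(all(idsOf(nineOut[1]) %in% idsOf(allOut[1])))
  expect_lt(length(idsOf(nineOut[1])), length(idsOf(allOut[1])))
})

test_that("reduction percentages report both remaining and removed fractions", {
  r <- summarizeReduction(26e6, 1.3e6)
  expect_equal(unname(r["remainingPercent"]), 5.0)
  expect_equal(unname(r["reductionPercent"]), 95.0)
  expect_equal(unname(summarizeReduction(100, 100)), c(100, 0))
  expect_equal(unname(summarizeReduction(100, 0)), c(0, 100))
  expect_error(summarizeReduction(0, 0), "undefined percentage")
})
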