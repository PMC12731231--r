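# Two-level call set: original plus all_hla copies with controlled edits.
twoLevelCallSet <- function(edits = list()) {
  base <- rbind(
    callRow("P01", "OptiType", "N", "A", "A*01:01", "A*24:02"),
    callRow("P01", "OptiType", "N", "B", "B*07:02", "B*44:02"),
    callRow("P01", "seq2HLA", "T", "A", "A*01:01", "A*24:02"),
    callRow("P02", "OptiType", "N", "A", "A*02:01", "A*02:01"),
    callRow("P02", "seq2HLA", "T", "A", "A*02:01", "A*03:01"))
  filt <- base
  filt$filterLevel <- "all_hla"
  for (e in edits) {
    filt[e$row, e$col] <- e$value
  }
  HLACallSet(rbind(base, filt))
}

test_that("genotype match counting is the maximum multiset intersection", {
  expect_equal(genotypeMatchCount(c("A*02:01", "A*03:01"),
                                  c("A*02:01", "A*03:01")), 2L)
  expect_equal(genotypeMatchCount(c("A*02:01", "A*02:01"),
                                  c("A*02:01", "A*03:01")), 1L)
  expect_equal(genotypeMatchCount(c("A*01:01", "A*24:02"),
                                  c("A*02:05", "A*30:01")), 0L)
  expect_equal(genotypeMatchCount(c("A*02:01", NA), c("A*02:01", "A*03:01")),
               1L)
  expect_equal(genotypeMatchCount(c("A*2:1", "A*3:1"),
                                  c("A*02:01", "A*03:01")), 2L)
  expect_error(genotypeMatchCount("A*02:01", "B*07:02"), "comparison error")
})

test_that("match counting is symmetric and bounded by 2 over random genotypes", {
  set.seed(51)
  pool <- sprintf("A*%02d:%02d", sample(1:60, 20, TRUE), sample(1:99, 20, TRUE))
  for (i in 1:300) {
    g1 <- sample(pool, 2, replace = TRUE)
    g2 <- sample(pool, 2, replace = TRUE)
    m <- genotypeMatchCount(g1, g2)
    expect_identical(m, genotypeMatchCount(g2, g1))
    expect_gte(m, 0L)
    expect_lte(m, 2L)
  }
})

test_that("identical filtered and original calls give 100% concordance in every grouping", {
  cs <- twoLevelCallSet()
  for (g in c("overall", "per_patient", "per_gene", "per_tool")) {
    rep <- concordance(cs, "all_hla", grouping = g)
    expect_true(all(rep$percent == 100), info = g)
  }
})

test_that("a single changed allele moves the group percentages by exactly its weight", {
  # P01 has 6 compared alleles over 3 cells; change one -> 5/6
  cs <- twoLevelCallSet(edits = list(
    list(row = 2, col = "allele2", value = "B*08:01")))
  pat <- concordance(cs, "all_hla", grouping = "per_patient")
  expect_equal(pat$percent[pat$groupKey == "P01"], 100 * 5 / 6)
  expect_equal(pat$percent[pat$groupKey == "P02"], 100)
  gene <- concordance(cs, "all_hla", grouping = "per_gene")
  expect_equal(gene$percent[gene$groupKey == "B"], 50)
  expect_equal(gene$percent[gene$groupKey == "A"], 100)
  overall <- concordance(cs, "all_hla")
  expect_equal(overall$matched, 9L)
  expect_equal(overall$compared, 10L)
  expect_equal(overall$percent, 90)
})

test_that("cells failed on either side drop out of numerator and denominator", {
  cs <- twoLevelCallSet(edits = list(
    list(row = 1, col = "status", value = "failed"),
    list(row = 1, col = "allele1", value = NA_character_),
    list(row = 1, col = "allele2", value = NA_character_)))
  overall <- concordance(cs, "all_hla")
  expect_equal(overall$compared, 8L)
  expect_equal(overall$percent, 100)
})

test_that("removing a discordant cell never lowers a group's concordance", {
  set.seed(52)
  alleles <- sprintf("A*02:%02d", 1:6)
  for (i in 1:40) {
    n <- 6L
    rows <- lapply(seq_len(n), function(j) {
      callRow("P01", "OptiType", c("N", "T", "R")[1 + (j %% 3)], "A",
              sample(alleles, 1), sample(alleles, 1))
    })
    base <- do.call(rbind, rows)
    base$tool <- rep(c("OptiType", "Polysolver"), each = 3)
    filt <- base
    filt$filterLevel <- "all_hla"
    flip <- sample(n, 1)
    pair <- sort(c(sample(alleles, 1), filt$allele2[flip]))
    filt$allele1[flip] <- pair[1]; filt$allele2[flip] <- pair[2]
    cs <- HLACallSet(rbind(base, filt))
    before <- concordance(cs, "all_hla")$percent
    matchPerCell <- vapply(seq_len(n), function(j) {
      genotypeMatchCount(c(base$allele1[j], base$allele2[j]),
                         c(filt$allele1[j], filt$allele2[j]))
    }, integer(1))
    discord <- which(matchPerCell < 2L)
    if (length(discord) == 0) next
    keep <- seq_len(n) != discord[1]
    cs2 <- HLACallSet(rbind(base[keep, ], filt[keep, ]))
    after <- concordance(cs2, "all_hla")$percent
    expect_gte(after, before)
  }
})

test_that("diversity ratio is 1 exactly when every cell is internally unanimous", {
  agree <- HLACallSet(rbind(
    callRow("P01", "OptiType", "N", "A", "A*02:01", "A*30:01"),
    callRow("P01", "OptiType", "T", "A", "A*02:01", "A*30:01"),
    callRow("P01", "OptiType", "R", "A", "A*02:01", "A*30:01")))
  r <- diversityRatio(agree, "OptiType")
  expect_equal(r$ratio, 1)
  expect_equal(r$cellCount, 2L)

  # 4 cells with distinct counts (1,1,2,1) -> ratio 1.25
  mixed <- HLACallSet(rbind(
    callRow("P01", "seq2HLA", "N", "A", "A*02:01", "A*30:01"),
    callRow("P01", "seq2HLA", "T", "A", "A*02:01", "A*31:01"),
    callRow("P02", "seq2HLA", "N", "A", "A*01:01", "A*24:02"),
    callRow("P02", "seq2HLA", "T", "A", "A*01:01", "A*24:02")))
  r2 <- diversityRatio(mixed, "seq2HLA")
  expect_equal(r2$cellCount, 4L)
  expect_equal(r2$distinctSum, 5L)
  expect_equal(r2$ratio, 1.25)

  single <- HLACallSet(callRow("P01", "OptiType", "N", "A",
                               "A*02:01", "A*02:01"))
  expect_equal(diversityRatio(single, "OptiType")$ratio, 1)
  expect_error(diversityRatio(single, "Polysolver"), "undefined ratio")
})

test_that("quality retention is the agreement rate of the confidence classification", {
  rows <- rbind(
    callRow("P01", "ATHLATES", "N", "A", "A*02:01", "A*03:01",
            qualityValue = 0),
    callRow("P01", "ATHLATES", "N", "B", "B*07:02", "B*44:02",
            qualityValue = 0),
    callRow("P01", "ATHLATES", "T", "A", "A*02:01", "A*03:01",
            qualityValue = 0),
    callRow("P01", "ATHLATES", "T", "B", "B*07:02", "B*44:02",
            qualityValue = 0))
  filt <- rows
  filt$filterLevel <- "all_hla"
  filt$qualityValue[2] <- 4  # one cell degrades confident -> not_confident
  cs <- HLACallSet(rbind(rows, filt))
  qr <- qualityRetention(cs, "ATHLATES", "all_hla")
  expect_equal(qr$comparable, 4L)
  expect_equal(qr$agreeing, 3L)
  expect_equal(qr$percent, 75)
  expect_error(qualityRetention(cs, "OptiType", "all_hla"),
               "unsupported tool")
})
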