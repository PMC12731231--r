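optitypeFixture <- function(path = tempfile(fileext = ".tsv")) {
  writeLines(c(
    "\tA1\tA2\tB1\tB2\tC1\tC2\tReads\tObjective",
    "0\tA*02:01\tA*03:01\tB*07:02\tB*44:02\tC*05:01\tC*07:02\t1000\t990.1"),
    path)
  path
}

polysolverFixture <- function(path = tempfile(fileext = ".txt")) {
  writeLines(c(
    "HLA-A\thla_a_02_01_01\thla_a_03_01",
    "HLA-B\thla_b_07_02_01\thla_b_07_02_01",
    "HLA-C\thla_c_05_01\thla_c_07_02"), path)
  path
}

seq2hlaFixture <- function(path = tempfile(fileext = ".tsv"),
                           classII = FALSE) {
  if (classII) {
    writeLines(c(
      "#Locus\tAllele 1\tConfidence\tAllele 2\tConfidence",
      "DQB1\tDQB1*06:02\t0.01\tDQB1*03:01\t0.21",
      "DRB1\tDRB1*15:01'\t0.001\tno\tNA"), path)
  } else {
    writeLines(c(
      "#Locus\tAllele 1\tConfidence\tAllele 2\tConfidence",
      "A\tA*02:01'\t0.003\tA*03:01\t0.004",
      "B\tB*07:02\t0.01\tB*44:02\t0.21",
      "C\tC*05:01\t0.001\tC*07:02\t0.002"), path)
  }
  path
}

athlatesFixture <- function(path = tempfile(fileext = ".txt"),
                            score = 0) {
  writeLines(c(
    "------------ Inferred Allelic Pairs -------------",
    "",
    sprintf("A*02:01:01\tA*03:01:01\t%g", score)), path)
  path
}

test_that("OptiType result rows become one two-field record per class I locus", {
  cs <- ingestToolOutput("OptiType", optitypeFixture(), "P01", "N", "original")
  df <- as.data.frame(callRecords(cs))
  expect_equal(nrow(df), 3L)
  expect_setequal(df$gene, c("A", "B", "C"))
  expect_equal(df$allele1[df$gene == "A"], "A*02:01")
  expect_true(all(df$qualityClass == "unavailable"))
  expect_true(all(df$status == "ok"))
})

test_that("Polysolver underscore alleles convert; homozygous output fills both slots", {
  cs <- ingestToolOutput("Polysolver", polysolverFixture(), "P01", "T",
                         "all_hla")
  df <- as.data.frame(callRecords(cs))
  expect_equal(df$allele1[df$gene == "A"], "A*02:01")
  expect_equal(df$allele2[df$gene == "A"], "A*03:01")
  expect_equal(df$allele1[df$gene == "B"], "B*07:02")
  expect_equal(df$allele2[df$gene == "B"], "B*07:02")
  expect_true(all(df$qualityClass == "unavailable"))
})

test_that("seq2HLA p-values set the confidence class; apostrophes and 'no' degrade gracefully", {
  cs <- ingestToolOutput("seq2HLA", seq2hlaFixture(), "P01", "R", "original")
  df <- as.data.frame(callRecords(cs))
  expect_equal(df$qualityClass[df$gene == "A"], "confident")    # worst p 0.004
  expect_equal(df$qualityClass[df$gene == "B"], "not_confident") # worst p 0.21
  cs2 <- ingestToolOutput("seq2HLA", seq2hlaFixture(classII = TRUE),
                          "P01", "R", "original")
  df2 <- as.data.frame(callRecords(cs2))
  expect_equal(df2$qualityValue[df2$gene == "DQB1"], 0.21)
  expect_equal(df2$qualityClass[df2$gene == "DQB1"], "not_confident")
  # 'no' second allele -> partial call, allele present in slot 1 only
  expect_equal(df2$allele1[df2$gene == "DRB1"], "DRB1*15:01")
  expect_true(is.na(df2$allele2[df2$gene == "DRB1"]))
})

test_that("ATHLATES allelic pairs reduce to two-field; score zero is confident", {
  cs <- ingestToolOutput("ATHLATES", athlatesFixture(score = 0), "P01", "N",
                         "original")
  df <- as.data.frame(callRecords(cs))
  expect_equal(sort(c(df$allele1, df$allele2)), c("A*02:01", "A*03:01"))
  expect_equal(df$qualityClass, "confident")
  cs2 <- ingestToolOutput("ATHLATES", athlatesFixture(score = 3), "P01", "N",
                          "original")
  expect_equal(as.data.frame(callRecords(cs2))$qualityClass, "not_confident")
})

test_that("ATHLATES on RNA-seq always yields failed records", {
  cs <- ingestToolOutput("ATHLATES", athlatesFixture(), "P01", "R",
                         "original", genes = "A")
  df <- as.data.frame(callRecords(cs))
  expect_equal(df$status, "failed")
  expect_true(is.na(df$allele1) && is.na(df$allele2))
})

test_that("empty or unusable files yield failed records per expected locus", {
  empty <- tempfile(); file.create(empty)
  cs <- ingestToolOutput("OptiType", empty, "P01", "N", "original")
  df <- as.data.frame(callRecords(cs))
  expect_equal(nrow(df), 3L)
  expect_true(all(df$status == "failed"))
  expect_error(ingestToolOutput("HLAscan", empty, "P01", "N", "original"),
               "unsupported tool")
  expect_error(ingestToolOutput("OptiType", tempfile(), "P01", "N",
                                "original"), "cannot read")
})

test_that("generic call TSV round-trips losslessly and validates its schema", {
  cs <- combineCallSets(
    ingestToolOutput("OptiType", optitypeFixture(), "P01", "N", "original"),
    ingestToolOutput("seq2HLA", seq2hlaFixture(), "P01", "R", "all_hla"),
    ingestToolOutput("ATHLATES", athlatesFixture(), "P01", "R", "original",
                     genes = "A"))
  path <- tempfile(fileext = ".tsv")
  writeGenericCalls(cs, path)
  back <- readGenericCalls(path)
  expect_identical(as.data.frame(callRecords(back)),
                   as.data.frame(callRecords(cs)))

  bad <- tempfile()
  writeLines("patient_id\ttool\tsource\tgene\tallele1\tallele2", bad)
  expect_error(readGenericCalls(bad), "schema error.*filter_level")
  bad2 <- tempfile()
  writeLines(c(paste("patient_id", "tool", "source", "filter_level", "gene",
                     "allele1", "allele2", "quality_value", "status",
                     sep = "\t"),
               paste("P01", "OptiType", "N", "original", "A",
                     "garbage!!", "A*02:01", "", "ok", sep = "\t")), bad2)
  expect_error(readGenericCalls(bad2), "line 2")
})

test_that("call-set invariants reject inconsistent records", {
  expect_error(HLACallSet(callRow("P01", "OptiType", "N", "A",
                                  "A*02:01", NA, status = "failed")),
               "failed records")
  expect_error(HLACallSet(callRow("P01", "OptiType", "N", "A",
                                  "B*07:02", "A*02:01")),
               "locus")
  expect_error(HLACallSet(callRow("P01", "OptiType", "N", "A",
                                  "A*02:01:01:01", "A*02:01")),
               "two-field")
  expect_error(
    HLACallSet(S4Vectors::DataFrame(
      patientId = "P01", tool = "seq2HLA", source = "N",
      filterLevel = "original", gene = "A", allele1 = "A*02:01",
      allele2 = "A*03:01", qualityValue = 0.2, qualityClass = "confident",
      status = "ok")),
    "quality rule")
})
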