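# Fixture builders shared across test files. Everything is generated in
# code at test time; no binary or stored data.

randomDNA <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Small IMGT-style FASTA: named vector allele -> sequence.
writeImgtFasta <- function(seqs, path, malformedHeaders = 0L) {
  lines <- character(0)
  acc <- 1L
  for (nm in names(seqs)) {
    lines <- c(lines,
               sprintf(">HLA:HLA%05d %s %d bp", acc, nm, nchar(seqs[[nm]])),
               seqs[[nm]])
    acc <- acc + 1L
  }
  for (i in seq_len(malformedHeaders)) {
    lines <- c(lines, ">this header has no allele token", randomDNA(60))
  }
  writeLines(lines, path)
  path
}

# Reference with one sequence per allele at several loci.
makeTestReference <- function(genes = c("A", "B", "C"), allelesPerGene = 2L,
                              len = 400L, seed = 11L) {
  set.seed(seed)
  seqs <- character(0)
  for (g in genes) {
    for (i in seq_len(allelesPerGene)) {
      seqs[[sprintf("%s*01:%02d", g, i)]] <- randomDNA(len)
    }
  }
  fa <- tempfile(fileext = ".fasta")
  writeImgtFasta(seqs, fa)
  readHLAReference(fa, "genomic")
}

writeFastqRecords <- function(names, seqs, path) {
  quals <- vapply(nchar(seqs), function(n) strrep("I", n), character(1))
  writeLines(as.vector(rbind(paste0("@", names), seqs, "+", quals)), path)
  path
}

# A call-record DataFrame row in one line.
callRow <- function(patientId, tool, source, gene, a1, a2,
                    filterLevel = "original", qualityValue = NA_real_,
                    status = "ok") {
  S4Vectors::DataFrame(patientId = patientId, tool = tool, source = source,
                       filterLevel = filterLevel, gene = gene,
                       allele1 = a1, allele2 = a2,
                       qualityValue = qualityValue, status = status)
}

# Call set voting a fixed allele vector at one patient/gene slot layout:
# each element of `votes1`/`votes2` fills one applicable class I cell in
# order OptiType/Polysolver/seq2HLA x N/T/R then ATHLATES x N/T.
classICells <- function() {
  app <- toolApplicability()
  app <- app[app$classI, c("tool", "source")]
  app[order(app$tool != "ATHLATES"), ]  # deterministic order, 11 rows
}

votesCallSet <- function(votes1, votes2, gene = "A", patientId = "P01",
                         filterLevel = "original") {
  cells <- classICells()
  stopifnot(length(votes1) <= nrow(cells))
  rows <- lapply(seq_along(votes1), function(i) {
    callRow(patientId, cells$tool[[i]], cells$source[[i]], gene,
            votes1[[i]], votes2[[i]], filterLevel = filterLevel)
  })
  HLACallSet(do.call(rbind, rows))
}
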