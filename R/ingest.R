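#' Ingest a typing tool's output file into normalized call records
#'
#' Format adapters for the four supported HLA-typing tools. Every allele is
#' reduced to canonical two-field form on the way in; unparseable fields
#' degrade to a partial or no-call slot rather than aborting, and an empty
#' or structurally unusable file yields one `status = "failed"` record per
#' expected locus. ATHLATES cannot process RNA-seq libraries, so
#' `tool = "ATHLATES", source = "R"` always yields failed records.
#'
#' Supported dialects:
#' \describe{
#'   \item{OptiType}{result TSV with columns `A1,A2,B1,B2,C1,C2` (first
#'     solution row is used).}
#'   \item{Polysolver}{`winners.hla.txt` lines
#'     `HLA-A<tab>hla_a_02_01_01<tab>hla_a_03_01`; underscore-coded names
#'     are converted to colon form. The same allele twice is a homozygous
#'     genotype.}
#'   \item{seq2HLA}{4-digit genotype TSV (`Locus`, `Allele 1`, `Confidence`,
#'     `Allele 2`, `Confidence`); trailing ambiguity apostrophes are
#'     stripped and the worse (larger) of the available p-values becomes
#'     the record's quality value.}
#'   \item{ATHLATES}{`.typing.txt`: the line block following
#'     `Inferred Allelic Pair(s)` holds `allele1 allele2 score`; score 0
#'     marks a confidently resolved pair.}
#' }
#'
#' @param tool `"OptiType"`, `"Polysolver"`, `"seq2HLA"` or `"ATHLATES"`.
#' @param path path to the tool's output file.
#' @param patientId patient identifier to stamp on the records.
#' @param source sequencing source: `"N"`, `"T"` or `"R"`.
#' @param filterLevel `"original"`, `"all_hla"` or `"nine_hla"`.
#' @param genes loci the run was expected to type (used to emit failed
#'   records when the file yields nothing). Defaults: A/B/C for OptiType
#'   and Polysolver; loci found in the file for seq2HLA and ATHLATES.
#' @return An [HLACallSet] with one record per locus.
#' @export
ingestToolOutput <- function(tool, path, patientId, source, filterLevel,
                             genes = NULL) {
  if (!tool %in% .TOOLS) stop("unsupported tool: ", tool)
  stopifnot(source %in% .SOURCES, filterLevel %in% .FILTER_LEVELS)
  if (!file.exists(path)) stop("cannot read tool output: ", path)

  parsed <- switch(tool,
    OptiType = .parseOptiType(path),
    Polysolver = .parsePolysolver(path),
    seq2HLA = .parseSeq2HLA(path),
    ATHLATES = .parseAthlates(path)
  )
  if (is.null(genes)) {
    genes <- if (nrow(parsed) > 0L) unique(parsed$gene)
             else if (tool %in% c("OptiType", "Polysolver")) hlaClassIGenes()
             else character(0)
  }
  genes <- toupper(sub("^HLA-", "", genes, ignore.case = TRUE))

  failAll <- tool == "ATHLATES" && source == "R"
  rows <- lapply(genes, function(g) {
    hit <- parsed[parsed$gene == g, , drop = FALSE]
    if (failAll || nrow(hit) == 0L) {
      data.frame(gene = g, allele1 = NA_character_, allele2 = NA_character_,
                 qualityValue = NA_real_, status = "failed")
    } else {
      hit <- hit[1L, , drop = FALSE]
      hit$status <- "ok"
      hit
    }
  })
  df <- do.call(rbind, rows)
  if (is.null(df) || nrow(df) == 0L) return(HLACallSet())
  slots <- .sortSlots(df$allele1, df$allele2)
  HLACallSet(S4Vectors::DataFrame(
    patientId = patientId, tool = tool, source = source,
    filterLevel = filterLevel, gene = df$gene,
    allele1 = slots$allele1, allele2 = slots$allele2,
    qualityValue = if (tool %in% c("OptiType", "Polysolver")) NA_real_
                   else df$qualityValue,
    status = df$status))
}

.safeNormalize <- function(x, dialect) {
  vapply(x, function(v) {
    tryCatch(.normalizeAllele(v, dialect = dialect),
             error = function(e) NA_character_)
  }, character(1), USE.NAMES = FALSE)
}

# gene/allele1/allele2/qualityValue rows from an OptiType result TSV
.parseOptiType <- function(path) {
  df <- tryCatch(utils::read.delim(path, colClasses = "character",
                                   check.names = FALSE),
                 error = function(e) NULL)
  empty <- data.frame(gene = character(0), allele1 = character(0),
                      allele2 = character(0), qualityValue = numeric(0))
  if (is.null(df) || nrow(df) == 0L) return(empty)
  rows <- lapply(c("A", "B", "C"), function(g) {
    c1 <- paste0(g, "1"); c2 <- paste0(g, "2")
    if (!all(c(c1, c2) %in% colnames(df))) return(NULL)
    data.frame(gene = g,
               allele1 = .safeNormalize(df[[c1]][1L], "optitype"),
               allele2 = .safeNormalize(df[[c2]][1L], "optitype"),
               qualityValue = NA_real_)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) empty else out
}

.parsePolysolver <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(lines, function(ln) {
    tok <- strsplit(trimws(ln), "[ \t]+")[[1L]]
    if (length(tok) < 2L) return(NULL)
    gene <- toupper(sub("^HLA-", "", tok[[1L]], ignore.case = TRUE))
    a1 <- .safeNormalize(tok[[2L]], "polysolver")
    a2 <- if (length(tok) >= 3L) .safeNormalize(tok[[3L]], "polysolver")
          else NA_character_
    data.frame(gene = gene, allele1 = a1, allele2 = a2,
               qualityValue = NA_real_)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    data.frame(gene = character(0), allele1 = character(0),
               allele2 = character(0), qualityValue = numeric(0))
  } else out
}

.parseSeq2HLA <- function(path) {
  df <- tryCatch(utils::read.delim(path, colClasses = "character",
                                   check.names = FALSE),
                 error = function(e) NULL)
  empty <- data.frame(gene = character(0), allele1 = character(0),
                      allele2 = character(0), qualityValue = numeric(0))
  if (is.null(df) || nrow(df) < 1L || ncol(df) < 5L) return(empty)
  do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
    gene <- toupper(sub("^#?Locus\\s*", "",
                        sub("^HLA-", "", df[[1L]][i], ignore.case = TRUE)))
    a1 <- .safeNormalize(df[[2L]][i], "seq2hla")
    p1 <- suppressWarnings(as.numeric(df[[3L]][i]))
    a2 <- .safeNormalize(df[[4L]][i], "seq2hla")
    p2 <- suppressWarnings(as.numeric(df[[5L]][i]))
    ps <- c(p1, p2)[!is.na(c(p1, p2))]
    data.frame(gene = gene, allele1 = a1, allele2 = a2,
               qualityValue = if (length(ps)) max(ps) else NA_real_)
  }))
}

.parseAthlates <- function(path) {
  lines <- readLines(path, warn = FALSE)
  start <- grep("Inferred Allelic Pair", lines, ignore.case = TRUE)
  empty <- data.frame(gene = character(0), allele1 = character(0),
                      allele2 = character(0), qualityValue = numeric(0))
  if (length(start) == 0L) return(empty)
  body <- lines[-seq_len(start[[1L]])]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0L) return(empty)
  rows <- lapply(body, function(ln) {
    tok <- strsplit(trimws(ln), "[ \t]+")[[1L]]
    if (length(tok) < 2L) return(NULL)
    a1 <- .safeNormalize(tok[[1L]], "athlates")
    a2 <- .safeNormalize(tok[[2L]], "athlates")
    score <- if (length(tok) >= 3L)
      suppressWarnings(as.numeric(tok[[3L]])) else NA_real_
    gene <- if (!is.na(a1)) parseAllele(a1)$gene
            else if (!is.na(a2)) parseAllele(a2)$gene else NA_character_
    if (is.na(gene)) return(NULL)
    data.frame(gene = gene, allele1 = a1, allele2 = a2, qualityValue = score)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  # first inferred pair per locus is the tool's genotype
  out[!duplicated(out$gene), , drop = FALSE]
}
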