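#' HLACallSet: normalized two-field HLA genotype calls
#'
#' One row per (patient, tool, sequencing source, filter level, locus):
#' the diploid two-field genotype the tool called there, an optional
#' quality value, and a run status. All allele text is normalized to
#' canonical two-field form at this boundary, so every downstream
#' comparison works on like-for-like names.
#'
#' Columns of the underlying [S4Vectors::DataFrame]:
#' \describe{
#'   \item{patientId}{sample/patient identifier.}
#'   \item{tool}{`"ATHLATES"`, `"OptiType"`, `"Polysolver"` or `"seq2HLA"`.}
#'   \item{source}{`"N"` (normal exome), `"T"` (tumor exome),
#'     `"R"` (tumor RNA-seq).}
#'   \item{filterLevel}{`"original"`, `"all_hla"` or `"nine_hla"`.}
#'   \item{gene}{locus symbol.}
#'   \item{allele1,allele2}{canonical two-field alleles; `NA` = no call at
#'     that slot. Homozygous genotypes repeat the allele. Slots are stored
#'     in lexicographic order of the canonical rendering.}
#'   \item{qualityValue}{ATHLATES typing score or seq2HLA p-value; `NA`
#'     where the tool reports none.}
#'   \item{qualityClass}{`"confident"` (ATHLATES score 0; seq2HLA p < 0.05),
#'     `"not_confident"`, or `"unavailable"` (OptiType, Polysolver, or no
#'     value reported).}
#'   \item{status}{`"ok"` or `"failed"` (tool did not produce a genotype;
#'     both allele slots are `NA`).}
#' }
#'
#' @slot calls the [S4Vectors::DataFrame] described above.
#' @seealso [ingestToolOutput()], [readGenericCalls()], [consensusCalls()]
#' @exportClass HLACallSet
setClass("HLACallSet", slots = c(calls = "DataFrame"))

.TOOLS <- c("ATHLATES", "OptiType", "Polysolver", "seq2HLA")
.SOURCES <- c("N", "T", "R")
.FILTER_LEVELS <- c("original", "all_hla", "nine_hla")
.CALL_COLUMNS <- c("patientId", "tool", "source", "filterLevel", "gene",
                   "allele1", "allele2", "qualityValue", "qualityClass",
                   "status")

#' Tool vocabulary
#' @return Character vector of the supported typing tools, sources or
#'   filter levels.
#' @export
hlaTools <- function() .TOOLS

#' @rdname hlaTools
#' @export
hlaSources <- function() .SOURCES

#' @rdname hlaTools
#' @export
hlaFilterLevels <- function() .FILTER_LEVELS

setValidity("HLACallSet", function(object) {
  df <- object@calls
  msgs <- character(0)
  if (!all(.CALL_COLUMNS %in% colnames(df))) {
    return(paste("missing column(s):",
                 paste(setdiff(.CALL_COLUMNS, colnames(df)), collapse = ", ")))
  }
  if (nrow(df) == 0L) return(TRUE)
  if (!all(df$tool %in% .TOOLS)) msgs <- c(msgs, "unknown tool tag")
  if (!all(df$source %in% .SOURCES)) msgs <- c(msgs, "source must be N, T or R")
  if (!all(df$filterLevel %in% .FILTER_LEVELS))
    msgs <- c(msgs, "filterLevel must be original, all_hla or nine_hla")
  if (!all(df$status %in% c("ok", "failed"))) msgs <- c(msgs, "bad status")
  if (!all(df$qualityClass %in% c("confident", "not_confident", "unavailable")))
    msgs <- c(msgs, "bad qualityClass")
  failed <- df$status == "failed"
  if (any(failed & (!is.na(df$allele1) | !is.na(df$allele2))))
    msgs <- c(msgs, "failed records must carry no alleles")
  if (any(df$tool %in% c("OptiType", "Polysolver") &
          df$qualityClass != "unavailable"))
    msgs <- c(msgs, "OptiType/Polysolver report no quality metric")
  conf <- which(df$qualityClass == "confident")
  if (length(conf)) {
    v <- df$qualityValue[conf]
    rule <- ifelse(df$tool[conf] == "ATHLATES", !is.na(v) & v == 0,
                   ifelse(df$tool[conf] == "seq2HLA", !is.na(v) & v < 0.05,
                          FALSE))
    if (!all(rule))
      msgs <- c(msgs, "confident records violate the tool's quality rule")
  }
  ok <- which(!failed)
  for (col in c("allele1", "allele2")) {
    al <- df[[col]][ok]
    al <- al[!is.na(al)]
    if (length(al)) {
      p <- tryCatch(parseAllele(al), error = function(e) NULL)
      if (is.null(p)) {
        msgs <- c(msgs, paste("unparseable allele text in", col))
      } else {
        if (any(lengths(p$fields) > 2L))
          msgs <- c(msgs, "alleles must be two-field normalized")
      }
    }
  }
  # alleles must share the record's locus
  for (col in c("allele1", "allele2")) {
    al <- df[[col]]
    has <- !is.na(al)
    if (any(has)) {
      g <- parseAllele(al[has])$gene
      if (!all(g == df$gene[has]))
        msgs <- c(msgs, paste("allele locus differs from record gene in", col))
    }
  }
  if (length(msgs)) unique(msgs) else TRUE
})

#' Construct an HLACallSet
#'
#' @param calls a data.frame or DataFrame with the columns documented in
#'   [HLACallSet-class]; `qualityValue`/`qualityClass` may be omitted
#'   (derived from tool and value; missing value = `"unavailable"`).
#' @return An [HLACallSet].
#' @export
HLACallSet <- function(calls = S4Vectors::DataFrame()) {
  df <- S4Vectors::DataFrame(calls)
  if (nrow(df) > 0L) {
    if (is.null(df$qualityValue)) df$qualityValue <- NA_real_
    df$qualityValue <- as.numeric(df$qualityValue)
    if (is.null(df$qualityClass)) {
      df$qualityClass <- .qualityClassOf(df$tool, df$qualityValue)
    }
    if (is.null(df$status)) df$status <- "ok"
    df <- df[, .CALL_COLUMNS]
  } else {
    df <- S4Vectors::DataFrame(
      patientId = character(0), tool = character(0), source = character(0),
      filterLevel = character(0), gene = character(0),
      allele1 = character(0), allele2 = character(0),
      qualityValue = numeric(0), qualityClass = character(0),
      status = character(0))
  }
  methods::new("HLACallSet", calls = df)
}

# Tool-specific confidence rule: ATHLATES score 0, seq2HLA p < 0.05.
.qualityClassOf <- function(tool, value) {
  ifelse(tool == "ATHLATES" & !is.na(value),
         ifelse(value == 0, "confident", "not_confident"),
         ifelse(tool == "seq2HLA" & !is.na(value),
                ifelse(value < 0.05, "confident", "not_confident"),
                "unavailable"))
}

# Order a genotype's two slots lexicographically (NA last).
.sortSlots <- function(allele1, allele2) {
  a <- cbind(allele1, allele2)
  swap <- (!is.na(a[, 2L]) & is.na(a[, 1L])) |
    (!is.na(a[, 1L]) & !is.na(a[, 2L]) & a[, 2L] < a[, 1L])
  a[swap, ] <- a[swap, c(2L, 1L), drop = FALSE]
  list(allele1 = a[, 1L], allele2 = a[, 2L])
}

#' @describeIn HLACallSet-class number of call records.
#' @param x,object an `HLACallSet`.
#' @export
setMethod("length", "HLACallSet", function(x) nrow(x@calls))

#' Call records as a DataFrame
#' @param x an [HLACallSet].
#' @return The underlying [S4Vectors::DataFrame].
#' @export
callRecords <- function(x) {
  stopifnot(methods::is(x, "HLACallSet"))
  x@calls
}

#' @export
#' @method as.data.frame HLACallSet
as.data.frame.HLACallSet <- function(x, ...) as.data.frame(x@calls, ...)

setMethod("show", "HLACallSet", function(object) {
  df <- object@calls
  cat(sprintf("HLACallSet: %d call records\n", nrow(df)))
  if (nrow(df) > 0L) {
    cat(sprintf("  patients: %d | loci: %s\n",
                length(unique(df$patientId)),
                paste(sort(unique(df$gene)), collapse = ", ")))
    cat(sprintf("  tools: %s\n",
                paste(sort(unique(df$tool)), collapse = ", ")))
    cat(sprintf("  levels: %s | failed: %d\n",
                paste(sort(unique(df$filterLevel)), collapse = ", "),
                sum(df$status == "failed")))
  }
})

#' Combine call sets
#' @param ... [HLACallSet] objects.
#' @return A single [HLACallSet] with rows concatenated.
#' @export
combineCallSets <- function(...) {
  sets <- list(...)
  stopifnot(all(vapply(sets, methods::is, logical(1), "HLACallSet")))
  HLACallSet(do.call(rbind, lapply(sets, callRecords)))
}

#' Read and write the canonical call TSV
#'
#' The interchange format has columns `patient_id`, `tool`, `source`,
#' `filter_level`, `gene`, `allele1`, `allele2`, `quality_value`, `status`
#' (tab-separated, header required; empty allele fields mean no call).
#' `qualityClass` is recomputed from tool and value on read, so a
#' write/read round trip is lossless.
#'
#' @param path TSV path.
#' @return `readGenericCalls()`: an [HLACallSet]. `writeGenericCalls()`:
#'   `path`, invisibly.
#' @export
readGenericCalls <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, colClasses = "character",
                          na.strings = c("NA", ""))
  need <- c("patient_id", "tool", "source", "filter_level", "gene",
            "allele1", "allele2", "quality_value", "status")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) {
    stop("schema error: missing column(s) ", paste(miss, collapse = ", "))
  }
  if (nrow(df) == 0L) return(HLACallSet())
  for (col in c("allele1", "allele2")) {
    vals <- df[[col]]
    bad <- integer(0)
    norm <- rep(NA_character_, length(vals))
    for (i in seq_along(vals)) {
      if (is.na(vals[[i]])) next
      norm[[i]] <- tryCatch(.normalizeAllele(vals[[i]]),
                            error = function(e) {
                              bad <<- c(bad, i); NA_character_
                            })
    }
    if (length(bad)) {
      stop("invalid allele text at line ", bad[[1L]] + 1L, " (", col, "): ",
           sQuote(vals[[bad[[1L]]]]))
    }
    df[[col]] <- norm
  }
  slots <- .sortSlots(df$allele1, df$allele2)
  HLACallSet(S4Vectors::DataFrame(
    patientId = df$patient_id, tool = df$tool, source = df$source,
    filterLevel = df$filter_level, gene = toupper(df$gene),
    allele1 = slots$allele1, allele2 = slots$allele2,
    qualityValue = suppressWarnings(as.numeric(df$quality_value)),
    status = df$status))
}

#' @rdname readGenericCalls
#' @param x an [HLACallSet].
#' @export
writeGenericCalls <- function(x, path) {
  df <- as.data.frame(callRecords(x))
  out <- data.frame(
    patient_id = df$patientId, tool = df$tool, source = df$source,
    filter_level = df$filterLevel, gene = df$gene,
    allele1 = df$allele1, allele2 = df$allele2,
    quality_value = df$qualityValue, status = df$status,
    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
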