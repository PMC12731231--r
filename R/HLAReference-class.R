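#' HLAReference: an HLA reference sequence database
#'
#' Container for a set of HLA allele sequences (genomic and/or cDNA) used
#' for HLA-targeted read filtering. Sequences live in a
#' [Biostrings::DNAStringSet]; per-record metadata (`allele`, `gene`,
#' `seqType`) is kept in its `mcols`. The `scope` records whether the set
#' covers all loci present in the source files (`"all_hla"`), exactly the
#' nine classical loci (`"nine_hla"`), or an arbitrary restriction
#' (`"custom"`).
#'
#' @slot sequences [Biostrings::DNAStringSet] with mcols columns `allele`
#'   (canonical full-resolution name), `gene` (locus symbol) and `seqType`
#'   (`"genomic"` or `"cDNA"`).
#' @slot scope one of `"all_hla"`, `"nine_hla"`, `"custom"`.
#' @slot versionLabel free-text database release label (e.g. `"3.51.0"`).
#' @slot skippedHeaders number of FASTA headers skipped on ingest because
#'   no allele name could be parsed from them.
#'
#' @seealso [readHLAReference()], [buildHLAReference()], [restrictToGenes()]
#' @exportClass HLAReference
setClass("HLAReference",
  slots = c(
    sequences = "DNAStringSet",
    scope = "character",
    versionLabel = "character",
    skippedHeaders = "integer"
  ),
  prototype = list(
    scope = "custom",
    versionLabel = "",
    skippedHeaders = 0L
  )
)

setValidity("HLAReference", function(object) {
  msgs <- character(0)
  mc <- S4Vectors::mcols(object@sequences)
  need <- c("allele", "gene", "seqType")
  if (is.null(mc) || !all(need %in% colnames(mc))) {
    return(paste("mcols must contain:", paste(need, collapse = ", ")))
  }
  if (length(object@sequences) == 0L) {
    msgs <- c(msgs, "empty reference: no sequence records")
  }
  if (any(Biostrings::width(object@sequences) == 0L)) {
    msgs <- c(msgs, "reference contains empty sequences")
  }
  if (anyDuplicated(paste(mc$allele, mc$seqType))) {
    msgs <- c(msgs, "duplicate (allele, seqType) records")
  }
  if (!object@scope %in% c("all_hla", "nine_hla", "custom")) {
    msgs <- c(msgs, "scope must be all_hla, nine_hla or custom")
  }
  if (object@scope == "nine_hla" &&
      !all(mc$gene %in% nineClassicalGenes())) {
    msgs <- c(msgs, "nine_hla scope with loci outside the nine classical genes")
  }
  if (!all(mc$seqType %in% c("genomic", "cDNA"))) {
    msgs <- c(msgs, "seqType must be 'genomic' or 'cDNA'")
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn HLAReference number of sequence records.
#' @param x,object an `HLAReference`.
#' @export
setMethod("length", "HLAReference", function(x) length(x@sequences))

#' Accessors for HLAReference
#'
#' `refSequences()` returns the [Biostrings::DNAStringSet] (records named by
#' canonical allele); `refAlleles()`, `refGenes()` the per-record allele
#' names and locus symbols; `refScope()` and `refVersion()` the database
#' scope and release label.
#'
#' @param x an `HLAReference`.
#' @return See individual descriptions.
#' @name HLAReference-accessors
#' @export
refSequences <- function(x) x@sequences

#' @rdname HLAReference-accessors
#' @export
refAlleles <- function(x) S4Vectors::mcols(x@sequences)$allele

#' @rdname HLAReference-accessors
#' @export
refGenes <- function(x) S4Vectors::mcols(x@sequences)$gene

#' @rdname HLAReference-accessors
#' @export
refScope <- function(x) x@scope

#' @rdname HLAReference-accessors
#' @export
refVersion <- function(x) x@versionLabel

setMethod("show", "HLAReference", function(object) {
  mc <- S4Vectors::mcols(object@sequences)
  cat(sprintf("HLAReference [%s] %s\n", object@scope,
              if (nzchar(object@versionLabel))
                paste0("(", object@versionLabel, ")") else ""))
  cat(sprintf("  %d records, %d loci: %s\n",
              length(object@sequences), length(unique(mc$gene)),
              paste(sort(unique(mc$gene)), collapse = ", ")))
  cat(sprintf("  seq types: %s\n",
              paste(names(table(mc$seqType)), table(mc$seqType),
                    sep = "=", collapse = ", ")))
  if (object@skippedHeaders > 0L)
    cat(sprintf("  skipped headers on ingest: %d\n", object@skippedHeaders))
})

# Allele-name token from an IPD-IMGT/HLA FASTA header
# ("HLA:HLA00001 A*01:01:01:01 3503 bp") or a plain allele-name header.
.alleleFromHeader <- function(headers) {
  vapply(headers, function(h) {
    for (tok in strsplit(trimws(h), "\\s+")[[1L]]) {
      p <- tryCatch(parseAllele(tok), error = function(e) NULL)
      if (!is.null(p) && !p$noCall[[1L]]) return(renderAllele(p))
    }
    NA_character_
  }, character(1), USE.NAMES = FALSE)
}

#' Read an IPD-IMGT/HLA-style FASTA file into an HLAReference
#'
#' Accepts the IPD-IMGT/HLA header convention
#' (`>HLA:HLA00001 A*01:01:01:01 3503 bp`) or plain allele-name headers.
#' Entries whose header yields no parseable allele name are skipped with a
#' warning and counted in the returned object. Sequences are uppercased;
#' records containing characters outside A/C/G/T/N are dropped with a
#' warning (downstream k-mer matching needs a clean alphabet).
#'
#' @param path FASTA file (plain or gzip-compressed).
#' @param seqType `"genomic"` or `"cDNA"`.
#' @param versionLabel optional free-text database release label.
#' @return An [HLAReference] with scope `"custom"`.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">HLA:HLA00001 A*01:01:01:01 8 bp", "ACGTACGT"), fa)
#' readHLAReference(fa, "genomic")
#' @export
readHLAReference <- function(path, seqType = c("genomic", "cDNA"),
                             versionLabel = "") {
  seqType <- match.arg(seqType)
  if (!file.exists(path)) stop("no such FASTA file: ", path)
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop("empty reference: no FASTA records in ", path)

  allele <- .alleleFromHeader(names(seqs))
  nskip <- sum(is.na(allele))
  if (nskip > 0L) {
    warning(nskip, " FASTA header(s) without a parseable allele name ",
            "skipped in ", path)
    seqs <- seqs[!is.na(allele)]
    allele <- allele[!is.na(allele)]
  }

  chars <- toupper(as.character(seqs))
  clean <- !grepl("[^ACGTN]", chars) & nzchar(chars)
  if (any(!clean)) {
    warning(sum(!clean), " record(s) with non-ACGTN characters dropped")
    chars <- chars[clean]
    allele <- allele[clean]
  }
  if (length(chars) == 0L) {
    stop("empty reference: no parseable records in ", path)
  }

  dss <- Biostrings::DNAStringSet(chars)
  names(dss) <- allele
  S4Vectors::mcols(dss) <- S4Vectors::DataFrame(
    allele = allele,
    gene = parseAllele(allele)$gene,
    seqType = seqType
  )
  methods::new("HLAReference", sequences = dss, scope = "custom",
               versionLabel = versionLabel, skippedHeaders = as.integer(nskip))
}

#' Build a combined genomic+cDNA HLA reference database
#'
#' Pools genomic ("gen") and coding ("nuc"/cDNA) FASTA files into a single
#' reference set, mirroring the All-HLA / 9-HLA database construction:
#' `scope = "all"` keeps every locus found; `scope = "nine"` restricts to
#' the nine classical loci (A, B, C, DPA1, DPB1, DQA1, DQB1, DRA, DRB1).
#'
#' @param genomicFiles character vector of genomic FASTA paths.
#' @param cdnaFiles character vector of cDNA FASTA paths.
#' @param scope `"all"` or `"nine"`.
#' @param versionLabel free-text release label (e.g. `"3.51.0"`).
#' @return An [HLAReference].
#' @export
buildHLAReference <- function(genomicFiles = character(0),
                              cdnaFiles = character(0),
                              scope = c("all", "nine"),
                              versionLabel = "") {
  scope <- match.arg(scope)
  parts <- c(
    lapply(genomicFiles, readHLAReference, seqType = "genomic"),
    lapply(cdnaFiles, readHLAReference, seqType = "cDNA")
  )
  if (length(parts) == 0L) stop("empty reference: no input FASTA files")
  db <- Reduce(.combineReferences, parts)
  db@scope <- "all_hla"
  db@versionLabel <- versionLabel
  if (scope == "nine") db <- restrictToGenes(db, nineClassicalGenes())
  methods::validObject(db)
  db
}

.combineReferences <- function(a, b) {
  seqs <- c(a@sequences, b@sequences)
  S4Vectors::mcols(seqs) <- rbind(S4Vectors::mcols(a@sequences),
                                  S4Vectors::mcols(b@sequences))
  methods::new("HLAReference", sequences = seqs, scope = "custom",
               versionLabel = a@versionLabel,
               skippedHeaders = a@skippedHeaders + b@skippedHeaders)
}

#' Restrict a reference database to a set of loci
#'
#' Keeps exactly the records whose locus is in `genes`, preserving record
#' order. The scope becomes `"nine_hla"` when `genes` equals the nine
#' classical loci, otherwise `"custom"`.
#'
#' @param db an [HLAReference].
#' @param genes non-empty character vector of locus symbols.
#' @return An [HLAReference]; error if no record survives.
#' @examples
#' \dontrun{nine <- restrictToGenes(db, nineClassicalGenes())}
#' @export
restrictToGenes <- function(db, genes) {
  stopifnot(methods::is(db, "HLAReference"), length(genes) > 0L)
  genes <- toupper(sub("^HLA-", "", genes, ignore.case = TRUE))
  keep <- refGenes(db) %in% genes
  if (!any(keep)) {
    stop("empty reference: no records for loci ",
         paste(genes, collapse = ", "))
  }
  seqs <- db@sequences[keep]
  S4Vectors::mcols(seqs) <- S4Vectors::mcols(db@sequences)[keep, , drop = FALSE]
  scope <- if (setequal(genes, nineClassicalGenes())) "nine_hla" else "custom"
  methods::new("HLAReference", sequences = seqs, scope = scope,
               versionLabel = db@versionLabel,
               skippedHeaders = db@skippedHeaders)
}

#' Write a reference database as FASTA
#'
#' Headers use the canonical form `>alleleName|seqType`.
#'
#' @param db an [HLAReference].
#' @param path output FASTA path (`.gz` suffix compresses).
#' @return `path`, invisibly.
#' @export
writeHLAReference <- function(db, path) {
  stopifnot(methods::is(db, "HLAReference"))
  mc <- S4Vectors::mcols(db@sequences)
  out <- db@sequences
  names(out) <- paste0(mc$allele, "|", mc$seqType)
  Biostrings::writeXStringSet(out, path,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}
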