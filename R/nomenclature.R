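#' @title HLA allele nomenclature
#'
#' @description Parsing, rendering and normalization of HLA allele names in
#' colon-delimited nomenclature (e.g. \code{"A*02:01:01:01"}). Allele names
#' carry a locus symbol, one to four numeric fields, and an optional
#' expression suffix (N, L, S, C, A, Q). Two-field resolution identifies a
#' distinct protein and is the working resolution throughout this package.
#'
#' @name hla-nomenclature
NULL

.HLA_CLASS_I <- c("A", "B", "C")
.HLA_CLASS_II <- c("DPA1", "DPB1", "DQA1", "DQB1", "DRA", "DRB1")
.EXPRESSION_SUFFIXES <- c("N", "L", "S", "C", "A", "Q")
.NO_CALL_TOKENS <- c("", "-", "no", "na", "n/a", "no call", "not typed", ".")

#' Classical HLA locus sets
#'
#' `hlaClassIGenes()` returns the classical class I loci (A, B, C);
#' `hlaClassIIGenes()` the classical class II loci (DPA1, DPB1, DQA1, DQB1,
#' DRA, DRB1); `nineClassicalGenes()` their union, the nine loci used to
#' build the restricted "9-HLA" reference database.
#'
#' @return Character vector of locus symbols (no "HLA-" prefix).
#' @examples
#' nineClassicalGenes()
#' @export
hlaClassIGenes <- function() .HLA_CLASS_I

#' @rdname hlaClassIGenes
#' @export
hlaClassIIGenes <- function() .HLA_CLASS_II

#' @rdname hlaClassIGenes
#' @export
nineClassicalGenes <- function() c(.HLA_CLASS_I, .HLA_CLASS_II)

#' HLA class of a locus symbol
#'
#' @param gene character vector of locus symbols (case-insensitive,
#'   "HLA-" prefix tolerated).
#' @return Character vector with elements `"I"`, `"II"`, or `NA` for loci
#'   outside the nine classical genes.
#' @examples
#' hlaClassOf(c("A", "DRB1", "MICA"))
#' @export
hlaClassOf <- function(gene) {
  g <- toupper(sub("^HLA-", "", gene, ignore.case = TRUE))
  ifelse(g %in% .HLA_CLASS_I, "I", ifelse(g %in% .HLA_CLASS_II, "II", NA))
}

# Underscore-coded allele (Polysolver style, "hla_a_02_01_01") -> star form.
.fromUnderscoreForm <- function(x) {
  parts <- strsplit(tolower(x), "_", fixed = TRUE)
  vapply(parts, function(p) {
    if (length(p) < 3L || p[[1L]] != "hla") return(NA_character_)
    gene <- toupper(p[[2L]])
    rest <- p[-(1:2)]
    # expression suffix may ride on the final field: "..._02n"
    m <- regmatches(rest[length(rest)],
                    regexec("^([0-9]+)([a-z])?$", rest[length(rest)]))[[1L]]
    if (length(m) == 0L) return(NA_character_)
    rest[length(rest)] <- m[[2L]]
    suffix <- if (nzchar(m[[3L]])) toupper(m[[3L]]) else ""
    if (!all(grepl("^[0-9]+$", rest))) return(NA_character_)
    paste0(gene, "*", paste(rest, collapse = ":"), suffix)
  }, character(1))
}

#' Parse HLA allele names
#'
#' Parses allele-name text in any of the dialects emitted by the supported
#' typing tools into a structured table. The "HLA-" prefix is stripped,
#' locus symbols are uppercased, and numeric field codes keep their leading
#' zeros as written. Recognized no-call tokens (`"no"`, `"-"`, empty) yield
#' a no-call row rather than an error; genuinely unparseable text is an
#' error naming the offending value.
#'
#' @param x character vector of allele names.
#' @param dialect input dialect. `"generic"` accepts standard nomenclature;
#'   `"seq2hla"` additionally strips trailing ambiguity apostrophes (the
#'   call is marked low-confidence); `"polysolver"` accepts underscore-coded
#'   names such as `"hla_a_02_01_01"`.
#' @return A [S4Vectors::DataFrame] with one row per input: `raw` (input
#'   text), `gene`, `fields` (a [IRanges::CharacterList] of digit codes),
#'   `suffix` (expression suffix or `""`), `noCall` (logical),
#'   `lowConfidence` (logical; apostrophe-marked seq2HLA calls).
#' @examples
#' parseAllele(c("A*02:01:01:01", "HLA-DRB1*15:01", "C*04:09N"))
#' @seealso [renderAllele()], [toTwoField()], [alleleKey()]
#' @export
parseAllele <- function(x, dialect = c("generic", "optitype", "polysolver",
                                       "seq2hla", "athlates")) {
  dialect <- match.arg(dialect)
  stopifnot(is.character(x))
  raw <- x
  x <- trimws(x)

  lowConf <- rep(FALSE, length(x))
  if (dialect == "seq2hla") {
    lowConf <- grepl("'$", x)
    x <- sub("'+$", "", x)
  }
  noCall <- is.na(x) | tolower(x) %in% .NO_CALL_TOKENS
  if (dialect == "polysolver") {
    conv <- .fromUnderscoreForm(x)
    x <- ifelse(!noCall & !is.na(conv), conv, x)
  }
  x <- sub("^HLA-", "", x, ignore.case = TRUE)

  pat <- "^([A-Za-z][A-Za-z0-9]*)\\*([0-9]+(?::[0-9]+)*)([NLSCAQnlscaq])?$"
  m <- regmatches(x, regexec(pat, x, perl = TRUE))
  ok <- lengths(m) == 4L
  bad <- !ok & !noCall
  if (any(bad)) {
    stop("invalid allele name(s): ",
         paste(sQuote(unique(raw[bad])), collapse = ", "))
  }

  gene <- rep(NA_character_, length(x))
  suffix <- rep(NA_character_, length(x))
  fields <- vector("list", length(x))
  for (i in which(ok)) {
    gene[[i]] <- toupper(m[[i]][[2L]])
    fields[[i]] <- strsplit(m[[i]][[3L]], ":", fixed = TRUE)[[1L]]
    suffix[[i]] <- toupper(m[[i]][[4L]])
  }
  fields[noCall] <- list(character(0))
  if (any(lengths(fields[ok]) > 4L)) {
    stop("allele name(s) with more than four fields: ",
         paste(sQuote(raw[ok][lengths(fields[ok]) > 4L]), collapse = ", "))
  }

  S4Vectors::DataFrame(
    raw = raw,
    gene = gene,
    fields = IRanges::CharacterList(fields),
    suffix = suffix,
    noCall = noCall,
    lowConfidence = lowConf
  )
}

#' Render parsed alleles to canonical text
#'
#' Canonical rendering is `GENE*FF:FF[:FF[:FF]][suffix]`, e.g. `"A*02:01"`
#' or `"C*04:09N"`. No-call rows render as `NA`.
#'
#' @param a a DataFrame from [parseAllele()], or a character vector (parsed
#'   with the generic dialect first).
#' @param prefix add the `"HLA-"` prefix on output.
#' @return Character vector of canonical allele names.
#' @examples
#' renderAllele(parseAllele("hla-a*02:01:01:01"))
#' @export
renderAllele <- function(a, prefix = FALSE) {
  a <- .asParsedAllele(a)
  out <- ifelse(
    a$noCall, NA_character_,
    paste0(a$gene, "*",
           vapply(as.list(a$fields), paste, character(1), collapse = ":"),
           ifelse(is.na(a$suffix), "", a$suffix))
  )
  if (prefix) out <- ifelse(is.na(out), out, paste0("HLA-", out))
  out
}

.asParsedAllele <- function(a, dialect = "generic") {
  if (is.character(a)) a <- parseAllele(a, dialect = dialect) else a
}

#' Reduce alleles to two-field resolution
#'
#' Truncates allele names to at most their first two fields (the
#' protein-level resolution), preserving the locus and any expression
#' suffix. The operation is idempotent; a one-field input is returned
#' unchanged (an under-resolved call).
#'
#' @param a parsed allele DataFrame or character vector of allele names.
#' @return Same shape as the input: a DataFrame if given one, otherwise a
#'   character vector of canonical two-field renderings.
#' @examples
#' toTwoField("A*02:01:01:01")
#' toTwoField("C*04:09N")
#' @export
toTwoField <- function(a) {
  chr <- is.character(a)
  a <- .asParsedAllele(a)
  a$fields <- IRanges::CharacterList(
    lapply(as.list(a$fields), function(f) f[seq_len(min(2L, length(f)))])
  )
  if (chr) renderAllele(a) else a
}

#' Equality key for allele comparison
#'
#' Leading zeros in field codes are display-only: tools differ in
#' zero-padding, so equality compares the numeric value of each field.
#' `alleleKey()` returns a normalized key (numeric fields, suffix retained)
#' on which two allele names compare equal iff they name the same allele.
#' Expression suffixes participate in equality: a null allele (N) is
#' functionally distinct from its expressed counterpart.
#'
#' @inheritParams renderAllele
#' @return Character vector of keys; `NA` for no-calls.
#' @examples
#' alleleKey("A*02:01") == alleleKey("A*2:1")
#' alleleKey("C*04:09N") == alleleKey("C*04:09")
#' @export
alleleKey <- function(a) {
  a <- .asParsedAllele(a)
  ifelse(
    a$noCall, NA_character_,
    paste0(a$gene, "*",
           vapply(as.list(a$fields), function(f) {
             paste(as.integer(f), collapse = ":")
           }, character(1)),
           ifelse(is.na(a$suffix), "", a$suffix))
  )
}

# Canonical two-field rendering of raw tool text; NA passes through.
.normalizeAllele <- function(x, dialect = "generic") {
  out <- rep(NA_character_, length(x))
  todo <- !is.na(x)
  if (any(todo)) {
    p <- parseAllele(x[todo], dialect = dialect)
    out[todo] <- renderAllele(toTwoField(p))
  }
  out
}
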