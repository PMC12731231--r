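#' Tool-by-source applicability for ensemble HLA calling
#'
#' Not every (tool, sequencing source) combination can type every locus:
#' class II loci are typed only by ATHLATES and seq2HLA, and ATHLATES
#' cannot process RNA-seq libraries at all. Under the full design — four
#' tools by three sources — a class I gene therefore has 11 call slots per
#' patient and a class II gene has 5.
#'
#' @param tools tools to consider (default all four).
#' @param sources sources to consider (default N, T, R).
#' @return A data.frame with columns `tool`, `source`, `classI`, `classII`
#'   (logical applicability flags).
#' @examples
#' toolApplicability()
#' @export
toolApplicability <- function(tools = hlaTools(), sources = hlaSources()) {
  stopifnot(length(tools) > 0L, length(sources) > 0L,
            all(tools %in% .TOOLS), all(sources %in% .SOURCES))
  grid <- expand.grid(tool = tools, source = sources,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  athlatesRNA <- grid$tool == "ATHLATES" & grid$source == "R"
  grid$classI <- !athlatesRNA
  grid$classII <- grid$tool %in% c("ATHLATES", "seq2HLA") & !athlatesRNA
  grid
}

#' Number of ensemble call slots available per gene
#'
#' Counts the (tool, source) combinations able to produce a genotype for a
#' gene of the given HLA class. With all four tools and all three sources
#' this is 11 for class I and 5 for class II.
#'
#' @param hlaClass `"I"` or `"II"`.
#' @inheritParams toolApplicability
#' @return Integer count.
#' @examples
#' expectedSlotCount("I")   # 11
#' expectedSlotCount("II", tools = c("ATHLATES", "seq2HLA"))  # 5
#' @export
expectedSlotCount <- function(hlaClass = c("I", "II"), tools = hlaTools(),
                              sources = hlaSources()) {
  hlaClass <- match.arg(hlaClass)
  app <- toolApplicability(tools, sources)
  sum(if (hlaClass == "I") app$classI else app$classII)
}

#' Long-format call matrix
#'
#' Expands an [HLACallSet] to one row per allele slot: keys
#' `(patientId, gene, slot, tool, source, filterLevel)` with the two-field
#' allele (`NA` for a no-call or failed run). Within each record the two
#' genotype slots are assigned by lexicographic order of the canonical
#' rendering, a deterministic pairing symmetric across tools; homozygous
#' genotypes fill both slots with the same allele. Duplicate cells (same
#' key from two records) resolve last-write-wins with a warning.
#'
#' @param x an [HLACallSet].
#' @return A data.frame with columns `patientId`, `gene`, `slot` (1 or 2),
#'   `tool`, `source`, `filterLevel`, `allele`, `status`, `qualityClass`.
#' @export
callMatrix <- function(x) {
  df <- as.data.frame(callRecords(x))
  if (nrow(df) == 0L) {
    return(data.frame(patientId = character(0), gene = character(0),
                      slot = integer(0), tool = character(0),
                      source = character(0), filterLevel = character(0),
                      allele = character(0), status = character(0),
                      qualityClass = character(0)))
  }
  key <- paste(df$patientId, df$gene, df$tool, df$source, df$filterLevel,
               sep = "\r")
  if (anyDuplicated(key)) {
    warning(sum(duplicated(key)),
            " duplicate call cell(s); keeping the last record of each")
    df <- df[!duplicated(key, fromLast = TRUE), , drop = FALSE]
  }
  slots <- .sortSlots(df$allele1, df$allele2)
  long <- rbind(
    data.frame(df[c("patientId", "gene", "tool", "source", "filterLevel",
                    "status", "qualityClass")],
               slot = 1L, allele = slots$allele1),
    data.frame(df[c("patientId", "gene", "tool", "source", "filterLevel",
                    "status", "qualityClass")],
               slot = 2L, allele = slots$allele2)
  )
  long <- long[order(long$patientId, long$gene, long$slot, long$tool,
                     long$source, long$filterLevel), ]
  rownames(long) <- NULL
  long[c("patientId", "gene", "slot", "tool", "source", "filterLevel",
         "allele", "status", "qualityClass")]
}

# Applicable (tool, source) pairs for one gene.
.applicableCells <- function(gene, tools, sources) {
  app <- toolApplicability(tools, sources)
  cls <- hlaClassOf(gene)
  ok <- if (is.na(cls)) app$classI & FALSE
        else if (cls == "I") app$classI else app$classII
  app[ok, c("tool", "source"), drop = FALSE]
}

.consensusOneSlot <- function(votes, expected, minSupportFraction) {
  total <- length(votes)
  if (total == 0L) {
    return(list(outcome = "no_call", allele = NA_character_,
                support = 0L, total = 0L, expected = expected))
  }
  keys <- alleleKey(votes)
  tab <- sort(table(keys), decreasing = TRUE)
  top <- as.integer(tab[[1L]])
  tied <- sum(tab == top) > 1L
  modalKey <- names(tab)[[1L]]
  modalAllele <- votes[match(modalKey, keys)]
  if (!tied && length(tab) == 1L && top == expected) {
    outcome <- "unanimous"
  } else if (tied) {
    outcome <- "ambiguous"
    modalAllele <- NA_character_
  } else if (top >= minSupportFraction * total) {
    outcome <- "consensus"
  } else {
    outcome <- "ambiguous"
    modalAllele <- NA_character_
  }
  list(outcome = outcome, allele = modalAllele, support = top,
       total = total, expected = expected)
}

#' Unanimous / consensus / ambiguous calls per allele slot
#'
#' For every (patient, gene, allele slot) the votes are the non-missing
#' two-field alleles across the applicable (tool, source) cells at one
#' filter level. A slot where every applicable cell voted for the same
#' allele is *unanimous* (high confidence); otherwise the modal allele is
#' the *consensus* provided it is unique and reaches
#' `minSupportFraction * total` votes; a tie for the modal allele is
#' *ambiguous*; no votes at all is *no_call*. Failed runs and no-calls
#' reduce the vote total but never create ambiguity by themselves.
#'
#' @param x an [HLACallSet].
#' @param filterLevel which filter level's calls to integrate (consensus is
#'   computed within one level at a time).
#' @param minSupportFraction minimal modal-vote fraction for a consensus
#'   call; default 0 (pure plurality with tie -> ambiguous).
#' @inheritParams toolApplicability
#' @return A data.frame with one row per (patientId, gene, slot):
#'   `outcome` (`unanimous`/`consensus`/`ambiguous`/`no_call`), `allele`,
#'   `support` (votes for the reported allele), `total` (votes cast),
#'   `expected` (applicable slots).
#' @examples
#' \dontrun{consensusCalls(calls, filterLevel = "original")}
#' @export
consensusCalls <- function(x, filterLevel = "original",
                           minSupportFraction = 0,
                           tools = hlaTools(), sources = hlaSources()) {
  stopifnot(filterLevel %in% .FILTER_LEVELS,
            minSupportFraction >= 0, minSupportFraction <= 1)
  long <- callMatrix(x)
  long <- long[long$filterLevel == filterLevel, , drop = FALSE]
  long <- long[long$tool %in% tools & long$source %in% sources, , drop = FALSE]

  units <- unique(long[c("patientId", "gene")])
  if (nrow(units) == 0L) {
    return(data.frame(patientId = character(0), gene = character(0),
                      slot = integer(0), outcome = character(0),
                      allele = character(0), support = integer(0),
                      total = integer(0), expected = integer(0)))
  }
  units <- units[order(units$patientId, units$gene), , drop = FALSE]

  unitKey <- paste(long$patientId, long$gene, sep = "\r")
  grpAllele <- split(long$allele, list(unitKey, long$slot), sep = "\r")
  grpCell <- split(paste(long$tool, long$source), list(unitKey, long$slot),
                   sep = "\r")

  res <- vector("list", 2L * nrow(units))
  pos <- 0L
  for (i in seq_len(nrow(units))) {
    pat <- units$patientId[[i]]
    gene <- units$gene[[i]]
    cells <- .applicableCells(gene, tools, sources)
    cellKeys <- paste(cells$tool, cells$source)
    expected <- nrow(cells)
    for (s in 1:2) {
      g <- paste(pat, gene, s, sep = "\r")
      votes <- grpAllele[[g]]
      applicable <- grpCell[[g]] %in% cellKeys
      votes <- votes[applicable & !is.na(votes)]
      r <- .consensusOneSlot(votes, expected, minSupportFraction)
      pos <- pos + 1L
      res[[pos]] <- list(patientId = pat, gene = gene, slot = s,
                         outcome = r$outcome, allele = r$allele,
                         support = r$support, total = r$total,
                         expected = r$expected)
    }
  }
  res <- res[seq_len(pos)]
  out <- data.frame(
    patientId = vapply(res, `[[`, character(1), "patientId"),
    gene = vapply(res, `[[`, character(1), "gene"),
    slot = vapply(res, `[[`, integer(1), "slot"),
    outcome = vapply(res, `[[`, character(1), "outcome"),
    allele = vapply(res, `[[`, character(1), "allele"),
    support = vapply(res, `[[`, integer(1), "support"),
    total = vapply(res, `[[`, integer(1), "total"),
    expected = vapply(res, `[[`, integer(1), "expected"))
  rownames(out) <- NULL
  out
}

#' Consensus for a single allele slot
#'
#' Convenience wrapper around [consensusCalls()] for one
#' (patient, gene, slot).
#'
#' @inheritParams consensusCalls
#' @param patientId,gene,slot the slot to resolve.
#' @return One-row data.frame as in [consensusCalls()]; error if the
#'   (patient, gene) pair is absent from the call set.
#' @export
consensusForSlot <- function(x, patientId, gene, slot,
                             filterLevel = "original",
                             minSupportFraction = 0,
                             tools = hlaTools(), sources = hlaSources()) {
  stopifnot(slot %in% 1:2)
  df <- as.data.frame(callRecords(x))
  if (!any(df$patientId == patientId & df$gene == gene)) {
    stop("no calls for patient ", patientId, ", gene ", gene)
  }
  all <- consensusCalls(x, filterLevel, minSupportFraction, tools, sources)
  all[all$patientId == patientId & all$gene == gene & all$slot == slot, ,
      drop = FALSE]
}
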