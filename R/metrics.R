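#' Matching alleles between two diploid genotypes
#'
#' The number of agreeing allele calls between two genotypes at the same
#' locus, counted as the size of the maximum multiset intersection of the
#' two allele multisets (0, 1 or 2 for full diploid calls; a homozygous
#' pair matches a heterozygous pair containing that allele once). Equality
#' is at two-field resolution with numeric field comparison, so differences
#' in zero-padding do not count as mismatches.
#'
#' @param g1,g2 character vectors of up to two allele names each (the
#'   genotype's allele multiset; `NA`s are dropped). Both must be at the
#'   same locus.
#' @return Integer in `0:2`.
#' @examples
#' genotypeMatchCount(c("A*02:01", "A*02:01"), c("A*02:01", "A*03:01"))
#' @export
genotypeMatchCount <- function(g1, g2) {
  g1 <- g1[!is.na(g1)]
  g2 <- g2[!is.na(g2)]
  stopifnot(length(g1) <= 2L, length(g2) <= 2L)
  if (length(g1) == 0L || length(g2) == 0L) return(0L)
  genes <- unique(c(parseAllele(g1)$gene, parseAllele(g2)$gene))
  if (length(genes) > 1L) {
    stop("comparison error: genotypes are at different loci (",
         paste(genes, collapse = ", "), ")")
  }
  t1 <- table(alleleKey(g1))
  t2 <- table(alleleKey(g2))
  shared <- intersect(names(t1), names(t2))
  sum(pmin(t1[shared], t2[shared]))
}

# Cell pairs (original vs filtered) with both sides ok, plus match counts.
.concordanceCells <- function(x, filterLevel) {
  stopifnot(filterLevel %in% c("all_hla", "nine_hla"))
  df <- as.data.frame(callRecords(x))
  orig <- df[df$filterLevel == "original" & df$status == "ok", , drop = FALSE]
  filt <- df[df$filterLevel == filterLevel & df$status == "ok", , drop = FALSE]
  if (nrow(orig) == 0L || nrow(filt) == 0L) {
    stop("concordance needs both 'original' and '", filterLevel, "' calls")
  }
  key <- function(d) paste(d$patientId, d$tool, d$source, d$gene, sep = "\r")
  m <- match(key(orig), key(filt))
  has <- !is.na(m)
  orig <- orig[has, , drop = FALSE]
  filt <- filt[m[has], , drop = FALSE]
  n <- nrow(orig)
  matched <- integer(n)
  compared <- integer(n)
  for (i in seq_len(n)) {
    g1 <- c(orig$allele1[[i]], orig$allele2[[i]])
    g2 <- c(filt$allele1[[i]], filt$allele2[[i]])
    matched[[i]] <- genotypeMatchCount(g1, g2)
    compared[[i]] <- max(sum(!is.na(g1)), sum(!is.na(g2)))
  }
  data.frame(patientId = orig$patientId, gene = orig$gene,
             tool = orig$tool, source = orig$source,
             matched = matched, compared = compared)
}

#' Concordance of filtered-reads-derived with original-reads-derived calls
#'
#' For every (patient, gene, tool, source) cell where both the original and
#' the filtered run produced a genotype, counts agreeing alleles
#' ([genotypeMatchCount()]) against alleles compared, then aggregates to
#' the requested grouping as `100 * matched / compared`. Cells missing on
#' either side (failed or absent runs) contribute to neither numerator nor
#' denominator; a group with no comparable cells is reported with `NA`
#' percent rather than dropped.
#'
#' @param x an [HLACallSet] containing `original` calls and calls at
#'   `filterLevel`.
#' @param filterLevel `"all_hla"` or `"nine_hla"` — the filtered side.
#' @param grouping `"overall"`, `"per_patient"`, `"per_gene"` or
#'   `"per_tool"`.
#' @return A data.frame with `grouping`, `groupKey`, `matched`, `compared`,
#'   `percent`, `filterLevel`.
#' @export
concordance <- function(x, filterLevel = c("all_hla", "nine_hla"),
                        grouping = c("overall", "per_patient", "per_gene",
                                     "per_tool")) {
  filterLevel <- match.arg(filterLevel)
  grouping <- match.arg(grouping)
  cells <- .concordanceCells(x, filterLevel)
  keys <- switch(grouping,
    overall = rep("overall", nrow(cells)),
    per_patient = cells$patientId,
    per_gene = cells$gene,
    per_tool = cells$tool
  )
  agg <- lapply(split(cells, keys), function(g) {
    data.frame(matched = sum(g$matched), compared = sum(g$compared))
  })
  out <- do.call(rbind, agg)
  out <- data.frame(grouping = grouping, groupKey = names(agg),
                    matched = out$matched, compared = out$compared,
                    percent = ifelse(out$compared > 0,
                                     100 * out$matched / out$compared,
                                     NA_real_),
                    filterLevel = filterLevel)
  rownames(out) <- NULL
  out
}

#' Call-diversity ratio of one tool across sequencing sources
#'
#' For a given tool and filter level, each (patient, gene, allele slot)
#' cell collects the alleles that tool called across its applicable
#' sequencing sources; the ratio is the total number of distinct alleles
#' over the number of cells with at least one call. A ratio of exactly 1
#' means the tool called the same allele from every source at every cell —
#' perfect internal agreement; larger values quantify source-dependent
#' instability of the tool's calls.
#'
#' @param x an [HLACallSet].
#' @param tool one of the four typing tools.
#' @param filterLevel filter level to assess.
#' @return A one-row data.frame: `tool`, `filterLevel`, `distinctSum`,
#'   `cellCount`, `ratio`.
#' @export
diversityRatio <- function(x, tool, filterLevel = "original") {
  stopifnot(tool %in% .TOOLS, filterLevel %in% .FILTER_LEVELS)
  long <- callMatrix(x)
  long <- long[long$tool == tool & long$filterLevel == filterLevel &
                 !is.na(long$allele), , drop = FALSE]
  if (nrow(long) == 0L) {
    stop("undefined ratio: no calls for ", tool, " at level ", filterLevel)
  }
  cellId <- paste(long$patientId, long$gene, long$slot, sep = "\r")
  distinct <- vapply(split(alleleKey(long$allele), cellId),
                     function(k) length(unique(k)), integer(1))
  data.frame(tool = tool, filterLevel = filterLevel,
             distinctSum = sum(distinct), cellCount = length(distinct),
             ratio = sum(distinct) / length(distinct))
}

#' Quality-metric retention after read filtering
#'
#' Of the two tools that report a quality metric (ATHLATES typing score;
#' seq2HLA p-value), how often does the filtered-reads run keep the same
#' binary quality classification (confident vs not) as the original-reads
#' run? Computed over cells where both runs produced a genotype with a
#' quality class; reported as a percentage. The retention arithmetic is a
#' classification agreement — the quality value itself may drift as long as
#' it stays on the same side of the tool's confidence rule.
#'
#' @param x an [HLACallSet].
#' @param tool `"ATHLATES"` or `"seq2HLA"` (the other tools report no
#'   quality metric and raise an error).
#' @param filterLevel `"all_hla"` or `"nine_hla"`.
#' @return A one-row data.frame: `tool`, `filterLevel`, `agreeing`,
#'   `comparable`, `percent`.
#' @export
qualityRetention <- function(x, tool = c("ATHLATES", "seq2HLA"),
                             filterLevel = c("all_hla", "nine_hla")) {
  tool <- tryCatch(match.arg(tool), error = function(e)
    stop("unsupported tool: only ATHLATES and seq2HLA report quality metrics"))
  filterLevel <- match.arg(filterLevel)
  df <- as.data.frame(callRecords(x))
  df <- df[df$tool == tool & df$status == "ok" &
             df$qualityClass != "unavailable", , drop = FALSE]
  orig <- df[df$filterLevel == "original", , drop = FALSE]
  filt <- df[df$filterLevel == filterLevel, , drop = FALSE]
  key <- function(d) paste(d$patientId, d$source, d$gene, sep = "\r")
  m <- match(key(orig), key(filt))
  has <- !is.na(m)
  if (!any(has)) {
    stop("undefined retention: no overlapping quality-bearing cells")
  }
  agree <- orig$qualityClass[has] == filt$qualityClass[m[has]]
  data.frame(tool = tool, filterLevel = filterLevel,
             agreeing = sum(agree), comparable = length(agree),
             percent = 100 * mean(agree))
}
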