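#' Run the filter -> ingest -> consensus -> metrics pipeline
#'
#' Orchestrates the package end-to-end from one configuration. The
#' configuration is a named list (or path to a YAML file with the same
#' keys):
#' \describe{
#'   \item{simulate}{optional list of [simConfig()] arguments; when
#'     present, reference, reads, truth and call tables are simulated and
#'     used as the run's inputs.}
#'   \item{reference}{list `genomic` / `cdna` (FASTA paths) and `scope`
#'     (`"all"` or `"nine"`) — used when not simulating.}
#'   \item{fastq}{list `r1`, `r2` — paired FASTQ to filter.}
#'   \item{calls}{path to a canonical call TSV ([readGenericCalls()]).}
#'   \item{k, minShared}{matcher parameters (defaults 21, 1).}
#'   \item{filterLevel}{level at which to compute consensus
#'     (default `"original"`).}
#'   \item{minSupportFraction}{consensus threshold (default 0).}
#'   \item{outDir}{output directory (created; default `tempfile()`).}
#' }
#'
#' Outputs written to `outDir`: filtered FASTQ pair + `filter_summary.tsv`
#' (when reads were filtered), `calls.tsv`, `consensus.tsv`, and — when the
#' call set contains both original and filtered levels — `concordance.tsv`.
#'
#' @param config named list or YAML file path.
#' @return Invisibly, a list with elements `outDir`, `summary`
#'   (a [FilterSummary] or `NULL`), `calls` (an [HLACallSet]),
#'   `consensus` (data.frame), `files` (named character vector).
#' @export
runPipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("validation error: no such config file: ",
                                   config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  outDir <- config$outDir %||% tempfile("hlaensemble_run_")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  k <- config$k %||% 21L
  minShared <- config$minShared %||% 1L
  level <- config$filterLevel %||% "original"
  files <- character(0)

  calls <- NULL
  summary <- NULL
  if (!is.null(config$simulate)) {
    cfg <- do.call(simConfig, config$simulate)
    ref <- simulateReference(cfg)
    refPath <- file.path(outDir, "reference.fasta")
    writeHLAReference(ref$db, refPath)
    sim <- simulateCohortReads(ref$db, cfg,
                               r1 = file.path(outDir, "reads_1.fastq"),
                               r2 = file.path(outDir, "reads_2.fastq"))
    utils::write.table(sim$truth, file.path(outDir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    idx <- kmerIndex(ref$db, k = k)
    summary <- filterPairs(sim$r1, sim$r2, idx,
                           file.path(outDir, "filtered_1.fastq"),
                           file.path(outDir, "filtered_2.fastq"),
                           minShared = minShared)
    calls <- simulateCallTables(sim$truth, cfg, filterLevel = level)
    files <- c(reference = refPath, truth = file.path(outDir, "truth.tsv"))
  } else {
    if (!is.null(config$fastq)) {
      for (p in unlist(config$fastq)) {
        if (!file.exists(p)) stop("validation error: no such FASTQ: ", p)
      }
      ref <- config$reference
      if (is.null(ref)) stop("validation error: fastq filtering needs a reference")
      for (p in c(ref$genomic, ref$cdna)) {
        if (!file.exists(p)) stop("validation error: no such FASTA: ", p)
      }
      db <- buildHLAReference(genomicFiles = ref$genomic %||% character(0),
                              cdnaFiles = ref$cdna %||% character(0),
                              scope = ref$scope %||% "all")
      idx <- kmerIndex(db, k = k)
      summary <- filterPairs(config$fastq$r1, config$fastq$r2, idx,
                             file.path(outDir, "filtered_1.fastq"),
                             file.path(outDir, "filtered_2.fastq"),
                             minShared = minShared)
    }
    if (!is.null(config$calls)) {
      if (!file.exists(config$calls)) {
        stop("validation error: no such calls TSV: ", config$calls)
      }
      calls <- readGenericCalls(config$calls)
    }
  }

  if (!is.null(summary)) {
    sdf <- as.data.frame(t(filterCounts(summary)))
    utils::write.table(sdf, file.path(outDir, "filter_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, filter_summary = file.path(outDir, "filter_summary.tsv"),
               filtered_r1 = file.path(outDir, "filtered_1.fastq"),
               filtered_r2 = file.path(outDir, "filtered_2.fastq"))
  }

  consensus <- NULL
  if (!is.null(calls)) {
    writeGenericCalls(calls, file.path(outDir, "calls.tsv"))
    files <- c(files, calls = file.path(outDir, "calls.tsv"))
    if (length(calls) == 0L) {
      warning("empty call set: consensus has no votes")
      consensus <- consensusCalls(HLACallSet(), filterLevel = level)
    } else {
      consensus <- consensusCalls(
        calls, filterLevel = level,
        minSupportFraction = config$minSupportFraction %||% 0)
    }
    utils::write.table(consensus, file.path(outDir, "consensus.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE, na = "")
    files <- c(files, consensus = file.path(outDir, "consensus.tsv"))

    df <- as.data.frame(callRecords(calls))
    filtLevels <- intersect(unique(df$filterLevel), c("all_hla", "nine_hla"))
    if ("original" %in% df$filterLevel && length(filtLevels)) {
      conc <- do.call(rbind, lapply(filtLevels, function(lv) {
        concordance(calls, filterLevel = lv, grouping = "overall")
      }))
      utils::write.table(conc, file.path(outDir, "concordance.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      files <- c(files, concordance = file.path(outDir, "concordance.tsv"))
    }
  }

  invisible(list(outDir = outDir, summary = summary, calls = calls,
                 consensus = consensus, files = files))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
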