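#' SimConfig: parameters of the synthetic HLA study generator
#'
#' The simulator emulates the inputs of an ensemble HLA-typing study whose
#' real counterpart (patient sequencing data) cannot be redistributed: an
#' HLA-like multi-gene, multi-allele reference, diploid truth genotypes for
#' a cohort, paired-end reads of HLA and background origin with sequencing
#' error, and per-tool call tables with a configurable per-slot error rate
#' and the known tool-by-source failure pattern (ATHLATES produces no
#' result from RNA-seq).
#'
#' @slot genes loci to simulate (locus symbols; class membership follows
#'   [hlaClassOf()]).
#' @slot allelesPerGene distinct alleles per locus (>= 2 if calls with
#'   error are wanted downstream).
#' @slot alleleLength allele sequence length in bases.
#' @slot mutationsPerAllele substitutions separating each allele from its
#'   locus ancestor.
#' @slot nPatients cohort size.
#' @slot readLength,meanInsert,sdInsert read and fragment geometry (bases).
#' @slot errorRate per-base substitution error rate of simulated reads.
#' @slot pairsPerHaplotype read pairs drawn per haplotype allele per locus.
#' @slot backgroundPairs non-HLA read pairs per patient (random sequence,
#'   screened against the reference so they share no 21-mer with it).
#' @slot callErrorRate per allele-slot probability that a tool calls a
#'   wrong allele of the same locus.
#' @slot lowQualityRate probability that a quality-reporting tool's record
#'   is emitted with a not-confident quality value.
#' @slot seed master seed; reference, truth genotypes, reads and call
#'   tables draw from seed, seed+1, seed+2, seed+3 so each stream is
#'   reproducible independently.
#' @seealso [simulateReference()], [simulateCohortReads()],
#'   [simulateCallTables()]
#' @exportClass SimConfig
setClass("SimConfig",
  slots = c(genes = "character", allelesPerGene = "integer",
            alleleLength = "integer", mutationsPerAllele = "integer",
            nPatients = "integer", readLength = "integer",
            meanInsert = "numeric", sdInsert = "numeric",
            errorRate = "numeric", pairsPerHaplotype = "integer",
            backgroundPairs = "integer", callErrorRate = "numeric",
            lowQualityRate = "numeric", seed = "integer")
)

setValidity("SimConfig", function(object) {
  msgs <- character(0)
  if (object@allelesPerGene < 1L) msgs <- c(msgs, "allelesPerGene must be >= 1")
  if (object@mutationsPerAllele >= object@alleleLength)
    msgs <- c(msgs, "configuration error: mutationsPerAllele must be < alleleLength")
  if (object@readLength > object@alleleLength)
    msgs <- c(msgs, "configuration error: readLength must be <= alleleLength")
  if (object@errorRate < 0 || object@errorRate > 1)
    msgs <- c(msgs, "errorRate must lie in [0, 1]")
  if (object@callErrorRate < 0 || object@callErrorRate > 1)
    msgs <- c(msgs, "callErrorRate must lie in [0, 1]")
  if (object@callErrorRate > 0 && object@allelesPerGene < 2L)
    msgs <- c(msgs, "configuration error: call errors need >= 2 alleles per gene")
  if (any(c(object@nPatients, object@pairsPerHaplotype,
            object@backgroundPairs) < 0L))
    msgs <- c(msgs, "counts must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Construct a simulation configuration
#'
#' Defaults describe a compact but realistic desk-scale study: three
#' class I loci with 6 alleles each of 1.2 kb, 100 bp paired reads on
#' ~300 bp fragments with a 0.1% base error rate, 5 pairs per haplotype
#' per locus, 100 background pairs per patient, and a 2% per-slot call
#' error.
#'
#' @param genes,allelesPerGene,alleleLength,mutationsPerAllele,nPatients
#'   see [SimConfig-class].
#' @param readLength,meanInsert,sdInsert,errorRate,pairsPerHaplotype see
#'   [SimConfig-class].
#' @param backgroundPairs,callErrorRate,lowQualityRate,seed see
#'   [SimConfig-class].
#' @return A validated [SimConfig].
#' @examples
#' simConfig(nPatients = 3)
#' @export
simConfig <- function(genes = hlaClassIGenes(), allelesPerGene = 6,
                      alleleLength = 1200, mutationsPerAllele = 15,
                      nPatients = 10, readLength = 100, meanInsert = 300,
                      sdInsert = 30, errorRate = 0.001,
                      pairsPerHaplotype = 5, backgroundPairs = 100,
                      callErrorRate = 0.02, lowQualityRate = 0.1,
                      seed = 42) {
  methods::new("SimConfig",
    genes = toupper(genes), allelesPerGene = as.integer(allelesPerGene),
    alleleLength = as.integer(alleleLength),
    mutationsPerAllele = as.integer(mutationsPerAllele),
    nPatients = as.integer(nPatients), readLength = as.integer(readLength),
    meanInsert = as.numeric(meanInsert), sdInsert = as.numeric(sdInsert),
    errorRate = as.numeric(errorRate),
    pairsPerHaplotype = as.integer(pairsPerHaplotype),
    backgroundPairs = as.integer(backgroundPairs),
    callErrorRate = as.numeric(callErrorRate),
    lowQualityRate = as.numeric(lowQualityRate), seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    "SimConfig: %d patients, loci %s (%d alleles x %d bp each)\n",
    object@nPatients, paste(object@genes, collapse = "/"),
    object@allelesPerGene, object@alleleLength))
  cat(sprintf(
    "  reads %d bp, insert %.0f+-%.0f, base error %.2g, %d pairs/haplotype, %d bg pairs\n",
    object@readLength, object@meanInsert, object@sdInsert,
    object@errorRate, object@pairsPerHaplotype, object@backgroundPairs))
  cat(sprintf("  call error %.2g, low-quality rate %.2g, seed %d\n",
              object@callErrorRate, object@lowQualityRate, object@seed))
})

.randomSeq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.mutate <- function(seq, positions) {
  ch <- strsplit(seq, "")[[1L]]
  for (p in positions) {
    ch[[p]] <- sample(setdiff(c("A", "C", "G", "T"), ch[[p]]), 1L)
  }
  paste(ch, collapse = "")
}

.simAlleleNames <- function(gene, n) sprintf("%s*01:%02d", gene, seq_len(n))

#' Simulate an HLA-like reference database
#'
#' Each locus gets an independent uniform-random ancestor sequence; each
#' allele is the ancestor with `mutationsPerAllele` substitutions at
#' distinct random positions. Allele names are synthetic two-field names
#' (`A*01:01`, `A*01:02`, ...). Identical seeds give byte-identical
#' output.
#'
#' @param cfg a [SimConfig].
#' @return A list: `db` (an [HLAReference], seqType `"genomic"`, scope per
#'   locus set) and `ancestors` (named character vector of the per-locus
#'   ancestor sequences).
#' @export
simulateReference <- function(cfg) {
  stopifnot(methods::is(cfg, "SimConfig"))
  set.seed(cfg@seed)
  ancestors <- stats::setNames(
    vapply(cfg@genes, function(g) .randomSeq(cfg@alleleLength), character(1)),
    cfg@genes)
  alleles <- character(0)
  seqs <- character(0)
  for (g in cfg@genes) {
    nm <- .simAlleleNames(g, cfg@allelesPerGene)
    for (i in seq_len(cfg@allelesPerGene)) {
      pos <- if (cfg@mutationsPerAllele > 0L)
        sample.int(cfg@alleleLength, cfg@mutationsPerAllele) else integer(0)
      seqs <- c(seqs, .mutate(ancestors[[g]], pos))
    }
    alleles <- c(alleles, nm)
  }
  dss <- Biostrings::DNAStringSet(seqs)
  names(dss) <- alleles
  S4Vectors::mcols(dss) <- S4Vectors::DataFrame(
    allele = alleles, gene = parseAllele(alleles)$gene, seqType = "genomic")
  scope <- if (setequal(cfg@genes, nineClassicalGenes())) "nine_hla"
           else "custom"
  db <- methods::new("HLAReference", sequences = dss, scope = scope,
                     versionLabel = "synthetic", skippedHeaders = 0L)
  list(db = db, ancestors = ancestors)
}

.patientIds <- function(n) sprintf("P%02d", seq_len(n))

#' Simulate diploid truth genotypes for a cohort
#'
#' Draws, per patient and locus, two alleles uniformly with replacement
#' (so homozygotes occur) from the simulated reference; slots are stored
#' in lexicographic order.
#'
#' @param db the [HLAReference] from [simulateReference()].
#' @param cfg the same [SimConfig].
#' @return A data.frame `patientId`, `gene`, `allele1`, `allele2`.
#' @export
simulateTruthGenotypes <- function(db, cfg) {
  stopifnot(methods::is(cfg, "SimConfig"))
  set.seed(cfg@seed + 1L)
  rows <- list()
  for (pat in .patientIds(cfg@nPatients)) {
    for (g in cfg@genes) {
      pool <- refAlleles(db)[refGenes(db) == g]
      pick <- sort(sample(pool, 2L, replace = TRUE))
      rows[[length(rows) + 1L]] <- data.frame(
        patientId = pat, gene = g, allele1 = pick[[1L]], allele2 = pick[[2L]])
    }
  }
  do.call(rbind, rows)
}

.applyBaseErrors <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "")[[1L]]
  hit <- which(stats::runif(length(ch)) < rate)
  for (p in hit) {
    ch[[p]] <- sample(setdiff(c("A", "C", "G", "T"), ch[[p]]), 1L)
  }
  paste(ch, collapse = "")
}

#' Simulate paired-end cohort reads with truth labels
#'
#' For every patient a diploid genotype per locus is drawn (via
#' [simulateTruthGenotypes()] under the same seed stream), then read pairs
#' are sampled from uniform fragment starts on each truth haplotype
#' (`pairsPerHaplotype` per locus), with per-base substitution errors at
#' `errorRate`. `backgroundPairs` additional pairs per patient are random
#' sequence, regenerated until they share no k-mer (k = 21) with the
#' reference, so their only property — not matching — holds by
#' construction. Each read name encodes its origin
#' (`sim|patient|gene|allele|i` or `sim|patient|bg|background|i`).
#'
#' @param db the [HLAReference] from [simulateReference()].
#' @param cfg the [SimConfig].
#' @param r1,r2 output FASTQ paths (default: files in `tempdir()`).
#' @return A list: `r1`, `r2` (paths), `truth` (data.frame as in
#'   [simulateTruthGenotypes()]), `origins` (data.frame `name`, `origin`
#'   with origin `"background"` or the source allele name).
#' @export
simulateCohortReads <- function(db, cfg,
                                r1 = tempfile(fileext = "_1.fastq"),
                                r2 = tempfile(fileext = "_2.fastq")) {
  stopifnot(methods::is(db, "HLAReference"), methods::is(cfg, "SimConfig"))
  truth <- simulateTruthGenotypes(db, cfg)
  set.seed(cfg@seed + 2L)
  refSeq <- stats::setNames(as.character(refSequences(db)), refAlleles(db))
  idx <- kmerIndex(db, k = 21L)
  rl <- cfg@readLength

  names1 <- character(0); seqs1 <- character(0)
  seqs2 <- character(0)
  origins <- character(0)

  emitPair <- function(frag) {
    fwd <- substr(frag, 1L, rl)
    rev <- .revcomp(substr(frag, nchar(frag) - rl + 1L, nchar(frag)))
    c(.applyBaseErrors(fwd, cfg@errorRate),
      .applyBaseErrors(rev, cfg@errorRate))
  }

  for (i in seq_len(nrow(truth))) {
    pat <- truth$patientId[[i]]; g <- truth$gene[[i]]
    for (hap in c(truth$allele1[[i]], truth$allele2[[i]])) {
      src <- refSeq[[hap]]
      L <- nchar(src)
      for (j in seq_len(cfg@pairsPerHaplotype)) {
        frag <- max(rl, min(L, round(stats::rnorm(1, cfg@meanInsert,
                                                  cfg@sdInsert))))
        start <- sample.int(L - frag + 1L, 1L)
        pair <- emitPair(substr(src, start, start + frag - 1L))
        nm <- sprintf("sim|%s|%s|%s|%d", pat, g, hap, length(names1) + 1L)
        names1 <- c(names1, nm)
        seqs1 <- c(seqs1, pair[[1L]]); seqs2 <- c(seqs2, pair[[2L]])
        origins <- c(origins, hap)
      }
    }
  }
  for (pat in unique(truth$patientId)) {
    for (j in seq_len(cfg@backgroundPairs)) {
      repeat {
        s1 <- .randomSeq(rl); s2 <- .randomSeq(rl)
        if (!any(readMatches(c(s1, s2), idx))) break
      }
      nm <- sprintf("sim|%s|bg|background|%d", pat, length(names1) + 1L)
      names1 <- c(names1, nm)
      seqs1 <- c(seqs1, s1); seqs2 <- c(seqs2, s2)
      origins <- c(origins, "background")
    }
  }

  .writeSimFastq <- function(seqs, names, path) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- names
    S4Vectors::mcols(x)$qualities <- Biostrings::BStringSet(
      vapply(nchar(seqs), function(n) strrep("I", n), character(1)))
    .writeFastq(x, path)
  }
  .writeSimFastq(seqs1, paste0(names1, "/1"), r1)
  .writeSimFastq(seqs2, paste0(names1, "/2"), r2)
  list(r1 = r1, r2 = r2, truth = truth,
       origins = data.frame(name = names1, origin = origins))
}

#' Simulate per-tool call tables from truth genotypes
#'
#' Emulates the tool-by-source call matrix: for every applicable
#' (tool, source) cell and locus, each truth allele is reported intact
#' with probability `1 - callErrorRate`, otherwise replaced by a uniformly
#' chosen different allele of the same locus. ATHLATES-by-RNA-seq cells
#' are emitted as failed records; class II loci are only typed by ATHLATES
#' and seq2HLA. Quality values are drawn consistently with each tool's
#' confidence rule (ATHLATES score 0 vs positive; seq2HLA p below vs above
#' 0.05), with `lowQualityRate` of records not confident.
#'
#' @param truth data.frame from [simulateTruthGenotypes()] (or the `truth`
#'   element of [simulateCohortReads()]).
#' @param cfg the [SimConfig].
#' @param filterLevel filter level to stamp on the records.
#' @param tools,sources the (tool, source) grid to emit.
#' @return An [HLACallSet].
#' @export
simulateCallTables <- function(truth, cfg, filterLevel = "original",
                               tools = hlaTools(), sources = hlaSources()) {
  stopifnot(methods::is(cfg, "SimConfig"), filterLevel %in% .FILTER_LEVELS)
  if (cfg@callErrorRate > 0 && cfg@allelesPerGene < 2L) {
    stop("configuration error: call errors need >= 2 alleles per gene")
  }
  set.seed(cfg@seed + 3L)
  app <- toolApplicability(tools, sources)
  allAlleles <- lapply(stats::setNames(nm = unique(truth$gene)),
                       function(g) .simAlleleNames(g, cfg@allelesPerGene))

  n <- nrow(truth) * nrow(app)
  out <- vector("list", n)
  pos <- 0L
  for (i in seq_len(nrow(truth))) {
    gene <- truth$gene[[i]]
    cls <- hlaClassOf(gene)
    for (j in seq_len(nrow(app))) {
      tool <- app$tool[[j]]; source <- app$source[[j]]
      applicable <- if (is.na(cls)) FALSE
                    else if (cls == "I") app$classI[[j]] else app$classII[[j]]
      # ATHLATES types both classes but produces nothing from RNA-seq:
      # that cell exists in the matrix as a failed run, not a gap.
      failedCell <- !is.na(cls) && tool == "ATHLATES" && source == "R"
      if (!applicable && !failedCell) next
      pos <- pos + 1L
      if (!applicable) {
        out[[pos]] <- data.frame(
          patientId = truth$patientId[[i]], tool = tool, source = source,
          filterLevel = filterLevel, gene = gene,
          allele1 = NA_character_, allele2 = NA_character_,
          qualityValue = NA_real_, status = "failed")
        next
      }
      call <- vapply(c(truth$allele1[[i]], truth$allele2[[i]]), function(a) {
        if (stats::runif(1) < cfg@callErrorRate) {
          sample(setdiff(allAlleles[[gene]], a), 1L)
        } else a
      }, character(1), USE.NAMES = FALSE)
      call <- sort(call)
      qv <- if (tool == "ATHLATES") {
        if (stats::runif(1) < cfg@lowQualityRate) sample(1:9, 1L) else 0
      } else if (tool == "seq2HLA") {
        if (stats::runif(1) < cfg@lowQualityRate)
          stats::runif(1, 0.05, 1) else stats::runif(1, 0, 0.049)
      } else NA_real_
      out[[pos]] <- data.frame(
        patientId = truth$patientId[[i]], tool = tool, source = source,
        filterLevel = filterLevel, gene = gene,
        allele1 = call[[1L]], allele2 = call[[2L]],
        qualityValue = qv, status = "ok")
    }
  }
  HLACallSet(do.call(rbind, out[seq_len(pos)]))
}
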