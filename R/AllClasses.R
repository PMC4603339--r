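#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importFrom stats setNames
#' @importClassesFrom S4Vectors DFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Simulation configuration for a synthetic allotetraploid study
#'
#' Holds every parameter of the synthetic data generator: the two diverged
#' subgenomes, the three-group two-replicate library design, planted
#' differential expression, and the sequencing model (2 x 101 bp pairs with
#' positional quality decay).
#'
#' @slot nGenes number of homoeolog gene pairs.
#' @slot geneLength integer length-2 vector, uniform range of transcript
#'   lengths in bp.
#' @slot divergence homoeolog divergence, substitutions per site in
#'   \[0, 0.25\].
#' @slot groups ordered group labels; the first is the reference
#'   (wild-type) group for planted effects.
#' @slot replicatesPerGroup libraries per group.
#' @slot readsPerLibrary read pairs simulated per library.
#' @slot readLength read length in bp.
#' @slot fragmentMean,fragmentSd fragment length distribution in bp.
#' @slot plantedUp,plantedDown named numeric vectors: gene id -> |log2 fold
#'   change| planted in the non-reference groups (down effects are applied
#'   as negative log2FC).
#' @slot dispersion negative-binomial dispersion of gene counts.
#' @slot seqErrorRate per-base substitution error rate.
#' @slot phredOffset 33 or 64.
#' @slot seed integer RNG seed; all generator randomness derives from it.
#' @exportClass SimConfig
setClass("SimConfig", representation(
  nGenes = "integer",
  geneLength = "integer",
  divergence = "numeric",
  groups = "character",
  replicatesPerGroup = "integer",
  readsPerLibrary = "integer",
  readLength = "integer",
  fragmentMean = "numeric",
  fragmentSd = "numeric",
  plantedUp = "numeric",
  plantedDown = "numeric",
  dispersion = "numeric",
  seqErrorRate = "numeric",
  phredOffset = "integer",
  seed = "integer"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@nGenes < 1L) msg <- c(msg, "nGenes must be positive")
  if (length(object@geneLength) != 2L || any(object@geneLength < 1L))
    msg <- c(msg, "geneLength must be two positive bounds")
  if (object@divergence < 0 || object@divergence > 0.25)
    msg <- c(msg, "divergence must lie in [0, 0.25]")
  if (length(object@groups) < 2L || anyDuplicated(object@groups))
    msg <- c(msg, "need at least two distinct group labels")
  if (object@replicatesPerGroup < 1L)
    msg <- c(msg, "replicatesPerGroup must be positive")
  if (object@readsPerLibrary < 1L)
    msg <- c(msg, "readsPerLibrary must be positive")
  if (object@readLength < 1L) msg <- c(msg, "readLength must be positive")
  if (object@readLength > min(object@geneLength))
    msg <- c(msg, "readLength must not exceed the minimum gene length")
  if (length(intersect(names(object@plantedUp), names(object@plantedDown))))
    msg <- c(msg, "plantedUp and plantedDown gene sets must be disjoint")
  if (any(object@plantedUp < 0) || any(object@plantedDown < 0))
    msg <- c(msg, "planted effect sizes are |log2FC| and must be >= 0")
  if (object@dispersion < 0) msg <- c(msg, "dispersion must be >= 0")
  if (object@seqErrorRate < 0 || object@seqErrorRate > 0.5)
    msg <- c(msg, "seqErrorRate must lie in [0, 0.5]")
  if (!object@phredOffset %in% c(33L, 64L))
    msg <- c(msg, "phredOffset must be 33 or 64")
  if (length(msg)) msg else TRUE
})

#' Construct a SimConfig
#'
#' @param nGenes number of homoeolog gene pairs.
#' @param geneLength length-2 numeric, bp range of transcript lengths.
#' @param divergence homoeolog divergence (substitutions/site).
#' @param groups ordered group labels; first label is the reference group.
#' @param replicatesPerGroup biological replicate libraries per group.
#' @param readsPerLibrary read pairs per library.
#' @param readLength read length (bp).
#' @param fragmentMean,fragmentSd fragment length model (bp).
#' @param plantedUp,plantedDown named numeric vectors gene id -> |log2FC|.
#' @param dispersion NB dispersion for simulated counts.
#' @param seqErrorRate per-base sequencing error rate.
#' @param phredOffset 33 or 64.
#' @param seed integer seed.
#' @return a validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(nGenes = 10, readsPerLibrary = 100, seed = 1)
#' @export
simConfig <- function(nGenes = 60L,
                      geneLength = c(600L, 2000L),
                      divergence = 0.05,
                      groups = c("wild", "landrace", "cultivar"),
                      replicatesPerGroup = 2L,
                      readsPerLibrary = 2000L,
                      readLength = 101L,
                      fragmentMean = 250,
                      fragmentSd = 40,
                      plantedUp = setNames(numeric(0), character(0)),
                      plantedDown = setNames(numeric(0), character(0)),
                      dispersion = 0.05,
                      seqErrorRate = 0.001,
                      phredOffset = 33L,
                      seed = 1L) {
  new("SimConfig",
      nGenes = as.integer(nGenes),
      geneLength = as.integer(geneLength),
      divergence = as.numeric(divergence),
      groups = as.character(groups),
      replicatesPerGroup = as.integer(replicatesPerGroup),
      readsPerLibrary = as.integer(readsPerLibrary),
      readLength = as.integer(readLength),
      fragmentMean = as.numeric(fragmentMean),
      fragmentSd = as.numeric(fragmentSd),
      plantedUp = plantedUp,
      plantedDown = plantedDown,
      dispersion = as.numeric(dispersion),
      seqErrorRate = as.numeric(seqErrorRate),
      phredOffset = as.integer(phredOffset),
      seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nGenes, "homoeolog pairs,",
      "divergence", object@divergence, "\n")
  cat("  design:", paste(object@groups, collapse = "/"),
      "x", object@replicatesPerGroup, "replicates;",
      object@readsPerLibrary, "pairs/library,",
      paste0("2x", object@readLength, "bp\n"))
  cat("  planted:", length(object@plantedUp), "up,",
      length(object@plantedDown), "down; dispersion",
      object@dispersion, "\n")
})

#' Quality-trimming parameters
#'
#' The cleaning rules applied to each read, in order: adapter clip, LEADING,
#' TRAILING, SLIDINGWINDOW, MINLEN (Trimmomatic semantics).
#'
#' @slot leadingQ drop 5' bases with quality below this phred score.
#' @slot trailingQ drop 3' bases with quality below this phred score.
#' @slot windowLen sliding window width in bases.
#' @slot windowQ minimum mean phred quality of a window.
#' @slot minLen reads shorter than this after trimming are discarded.
#' @slot adapters adapter sequences clipped from read 3' ends.
#' @slot phredOffset 33 or 64.
#' @exportClass TrimParams
setClass("TrimParams", representation(
  leadingQ = "integer", trailingQ = "integer",
  windowLen = "integer", windowQ = "numeric",
  minLen = "integer", adapters = "character",
  phredOffset = "integer"
))

setValidity("TrimParams", function(object) {
  msg <- character()
  if (object@leadingQ < 0L || object@trailingQ < 0L)
    msg <- c(msg, "quality thresholds must be >= 0")
  if (object@windowLen < 1L) msg <- c(msg, "windowLen must be >= 1")
  if (object@minLen < 1L) msg <- c(msg, "minLen must be >= 1")
  if (!object@phredOffset %in% c(33L, 64L))
    msg <- c(msg, "phredOffset must be 33 or 64")
  if (length(msg)) msg else TRUE
})

#' Construct TrimParams
#'
#' Defaults are LEADING:3 TRAILING:3 SLIDINGWINDOW:4:20 MINLEN:40 with the
#' bundled TruSeq adapters.
#'
#' @param leadingQ,trailingQ,windowLen,windowQ,minLen see
#'   [TrimParams-class].
#' @param adapters character vector of adapter sequences; defaults to the
#'   TruSeq adapters shipped in `extdata/adapters_truseq.fa`.
#' @param phredOffset 33 or 64.
#' @return a [TrimParams-class] object.
#' @export
trimParams <- function(leadingQ = 3L, trailingQ = 3L, windowLen = 4L,
                       windowQ = 20, minLen = 40L,
                       adapters = defaultAdapters(), phredOffset = 33L) {
  new("TrimParams", leadingQ = as.integer(leadingQ),
      trailingQ = as.integer(trailingQ), windowLen = as.integer(windowLen),
      windowQ = as.numeric(windowQ), minLen = as.integer(minLen),
      adapters = as.character(adapters), phredOffset = as.integer(phredOffset))
}

#' Bundled Illumina TruSeq adapter sequences
#' @return character vector of adapter sequences.
#' @export
defaultAdapters <- function() {
  fa <- system.file("extdata", "adapters_truseq.fa", package = "homeoseq")
  if (!nzchar(fa)) return(character(0))
  as.character(Biostrings::readDNAStringSet(fa))
}

setMethod("show", "TrimParams", function(object) {
  cat(sprintf(
    "TrimParams: LEADING:%d TRAILING:%d SLIDINGWINDOW:%d:%g MINLEN:%d phred%d; %d adapter(s)\n",
    object@leadingQ, object@trailingQ, object@windowLen, object@windowQ,
    object@minLen, object@phredOffset, length(object@adapters)))
})

#' Fragment counts with a group design
#'
#' A [SummarizedExperiment::SummarizedExperiment-class] carrying one
#' `counts` assay (genes x libraries, non-negative integers) and a `group`
#' column in `colData` assigning each library to one genotype group.
#'
#' @exportClass HomeologCounts
setClass("HomeologCounts", contains = "SummarizedExperiment")

setValidity("HomeologCounts", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "must carry a 'counts' assay")
  else {
    cnt <- SummarizedExperiment::assay(object, "counts")
    if (any(cnt < 0)) msg <- c(msg, "counts must be non-negative")
    if (any(cnt != round(cnt))) msg <- c(msg, "counts must be integral")
  }
  if (!"group" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData must contain a 'group' column")
  if (length(msg)) msg else TRUE
})

#' Construct a HomeologCounts object
#'
#' @param counts genes x libraries matrix of non-negative integer fragment
#'   counts.
#' @param group character/factor of length `ncol(counts)` assigning each
#'   library to a genotype group.
#' @param ... further arguments passed to
#'   [SummarizedExperiment::SummarizedExperiment()] (e.g. `metadata`).
#' @return a [HomeologCounts-class] object.
#' @examples
#' m <- matrix(rpois(20, 10), nrow = 5,
#'             dimnames = list(paste0("g", 1:5), paste0("lib", 1:4)))
#' hc <- homeologCounts(m, group = c("wild", "wild", "cultivar", "cultivar"))
#' @export
homeologCounts <- function(counts, group, ...) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(group = factor(group)), ...)
  new("HomeologCounts", se)
}

setMethod("show", "HomeologCounts", function(object) {
  cat("HomeologCounts:", nrow(object), "genes x", ncol(object),
      "libraries\n")
  cat("  groups:", paste(sprintf(
    "%s(%d)", levels(groups(object)), table(groups(object))),
    collapse = ", "), "\n")
})

#' Differential expression results table
#'
#' A `DFrame` with one row per gene: per-group base means (means of
#' size-factor-normalised counts), log2 fold change of each non-reference
#' group against the reference group, raw and Benjamini-Hochberg adjusted
#' p values, and the UP/DOWN/NS call at the configured thresholds.
#' Thresholds are recorded in `metadata()`.
#'
#' @exportClass DEResults
setClass("DEResults", contains = "DFrame")

setMethod("show", "DEResults", function(object) {
  md <- metadata(object)
  cat("DEResults:", nrow(object), "genes;",
      sprintf("thresholds |log2FC| >= %g, FDR <= %g\n",
              md$lfcThreshold, md$alpha))
  show(S4Vectors::DataFrame(as(object, "DFrame")))
})
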