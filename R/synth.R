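# Synthetic allotetraploid study generator: diverged subgenomes, gene
# models, NB counts with planted effects, paired reads with truth labels.

#' Simulate two diverged homoeologous subgenomes
#'
#' Draws an ancestral transcript per gene, keeps it as the subgenome-A copy
#' and derives the subgenome-B copy by iid substitutions at the configured
#' divergence rate (every substitution changes the base, so the per-site
#' Hamming distance between homoeologs is Binomial(length, divergence)).
#' Each transcript is one single-exon gene on its own contig.
#'
#' @param cfg a [SimConfig-class] object.
#' @return a list with `refA`, `refB`
#'   ([Biostrings::DNAStringSet-class] per subgenome),
#'   `geneModels` ([GenomicRanges::GRanges-class] over both subgenomes with
#'   `gene_id` and `subgenome` metadata columns) and `pairs`
#'   (data.frame of homoeolog pair identities).
#' @examples
#' sg <- simulateSubgenomes(simConfig(nGenes = 5, seed = 7))
#' length(sg$refA)
#' @export
simulateSubgenomes <- function(cfg) {
  validObject(cfg)
  set.seed(cfg@seed)
  geneIds <- sprintf("g%04d", seq_len(cfg@nGenes))
  lens <- sample(seq(cfg@geneLength[1], cfg@geneLength[2]), cfg@nGenes,
                 replace = TRUE)
  bases <- c("A", "C", "G", "T")
  seqA <- vapply(lens, function(L)
    paste(sample(bases, L, replace = TRUE), collapse = ""), character(1))
  seqB <- vapply(seqA, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    hit <- which(stats::runif(length(ch)) < cfg@divergence)
    if (length(hit)) {
      ch[hit] <- vapply(ch[hit], function(b)
        sample(setdiff(bases, b), 1L), character(1))
    }
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)

  refA <- Biostrings::DNAStringSet(seqA)
  names(refA) <- paste0(geneIds, "_A")
  refB <- Biostrings::DNAStringSet(seqB)
  names(refB) <- paste0(geneIds, "_B")

  gm <- GenomicRanges::GRanges(
    seqnames = c(names(refA), names(refB)),
    ranges = IRanges::IRanges(start = 1L, width = rep(lens, 2L)),
    strand = "+",
    gene_id = c(names(refA), names(refB)),
    subgenome = rep(c("A", "B"), each = cfg@nGenes))
  pairs <- data.frame(gene = geneIds,
                      gene_A = names(refA), gene_B = names(refB),
                      length = lens, stringsAsFactors = FALSE)
  list(refA = refA, refB = refB, geneModels = gm, pairs = pairs)
}

#' Simulate a negative-binomial count matrix with planted effects
#'
#' Gene baseline means are log-normal; libraries get mild size factors;
#' counts are NB with the configured dispersion (Poisson in the zero
#' dispersion limit). Genes in `plantedUp`/`plantedDown` have their means
#' in every non-reference group scaled by `2^(log2FC)` relative to the
#' reference (first) group.
#'
#' @param cfg a [SimConfig-class] object.
#' @param baseMeans optional numeric vector of reference-group means per
#'   gene; drawn log-normally when `NULL`.
#' @return a [HomeologCounts-class] object whose `metadata()` records the
#'   ground truth: `trueLog2FC`, `deStatus` (up/down/null per gene) and the
#'   library size factors used.
#' @examples
#' hc <- simulateCounts(simConfig(nGenes = 20, seed = 3))
#' metadata(hc)$deStatus[1:5]
#' @export
simulateCounts <- function(cfg, baseMeans = NULL) {
  validObject(cfg)
  set.seed(cfg@seed + 1L)
  geneIds <- sprintf("g%04d", seq_len(cfg@nGenes))
  if (is.null(baseMeans))
    baseMeans <- stats::rlnorm(cfg@nGenes, meanlog = log(150), sdlog = 1)
  trueLfc <- setNames(numeric(cfg@nGenes), geneIds)
  up <- intersect(names(cfg@plantedUp), geneIds)
  dn <- intersect(names(cfg@plantedDown), geneIds)
  trueLfc[up] <- cfg@plantedUp[up]
  trueLfc[dn] <- -cfg@plantedDown[dn]
  status <- setNames(rep("null", cfg@nGenes), geneIds)
  status[up] <- "up"; status[dn] <- "down"

  nLib <- length(cfg@groups) * cfg@replicatesPerGroup
  group <- rep(cfg@groups, each = cfg@replicatesPerGroup)
  libNames <- paste0(group, "_", rep(seq_len(cfg@replicatesPerGroup),
                                     times = length(cfg@groups)))
  sf <- stats::runif(nLib, 0.7, 1.3)

  mu <- outer(baseMeans, rep(1, nLib))
  nonref <- group != cfg@groups[1]
  mu[, nonref] <- mu[, nonref] * 2^trueLfc
  mu <- sweep(mu, 2, sf, `*`)

  cnt <- matrix(0L, cfg@nGenes, nLib,
                dimnames = list(geneIds, libNames))
  for (j in seq_len(nLib)) {
    cnt[, j] <- if (cfg@dispersion > 0)
      stats::rnbinom(cfg@nGenes, mu = mu[, j], size = 1 / cfg@dispersion)
    else stats::rpois(cfg@nGenes, lambda = mu[, j])
  }
  homeologCounts(cnt, group = group,
                 metadata = list(trueLog2FC = trueLfc, deStatus = status,
                                 librarySizeFactors = sf,
                                 referenceGroup = cfg@groups[1]))
}

#' Simulate paired-end reads with a ground-truth table
#'
#' For each library, fragments are drawn from genes in proportion to the
#' library's expression column; each fragment comes from the A or B
#' homoeolog copy with equal probability (recorded in the truth table).
#' Mate 1 is the fragment 5' end, mate 2 the reverse complement of its 3'
#' end. Base qualities follow a linear mean decline from Q38 to Q22 along
#' the read with Gaussian jitter (sd 3, clamped to \[2, 40\]); sequencing
#' errors are iid substitutions at `seqErrorRate`.
#'
#' @param cfg a [SimConfig-class] object.
#' @param subgenomes output of [simulateSubgenomes()].
#' @param expression a [HomeologCounts-class] object (expression weights per
#'   library), typically from [simulateCounts()] under the same config.
#' @return a list with `libraries` (per library: `id`, `seq1`, `qual1`,
#'   `seq2`, `qual2`) and `truth` (data.frame: `read_id`, `library`,
#'   `gene`, `origin` in A/B).
#' @export
simulateReads <- function(cfg, subgenomes, expression) {
  validObject(cfg)
  stopifnot(is(expression, "HomeologCounts"))
  set.seed(cfg@seed + 2L)
  cnt <- counts(expression)
  stopifnot(nrow(cnt) == nrow(subgenomes$pairs))
  seqA <- as.character(subgenomes$refA)
  seqB <- as.character(subgenomes$refB)
  lens <- subgenomes$pairs$length
  L <- cfg@readLength
  meanQ <- seq(38, 22, length.out = L)

  libs <- vector("list", ncol(cnt))
  names(libs) <- colnames(cnt)
  truth <- vector("list", ncol(cnt))
  resampled <- 0L

  for (j in seq_len(ncol(cnt))) {
    n <- cfg@readsPerLibrary
    w <- cnt[, j]
    if (sum(w) == 0) w <- rep(1, length(w))
    geneIdx <- sample.int(nrow(cnt), n, replace = TRUE, prob = w)
    origin <- sample(c("A", "B"), n, replace = TRUE)
    flen <- pmax(L, round(stats::rnorm(n, cfg@fragmentMean, cfg@fragmentSd)))
    over <- flen > lens[geneIdx]
    resampled <- resampled + sum(over)
    flen[over] <- lens[geneIdx[over]]
    start <- 1L + floor(stats::runif(n) * (lens[geneIdx] - flen + 1))
    src <- ifelse(origin == "A", seqA[geneIdx], seqB[geneIdx])
    frag <- substr(src, start, start + flen - 1L)
    s1 <- substr(frag, 1L, L)
    s2 <- revComp(substr(frag, flen - L + 1L, flen))
    if (cfg@seqErrorRate > 0) {
      s1 <- injectErrors(s1, cfg@seqErrorRate)
      s2 <- injectErrors(s2, cfg@seqErrorRate)
    }
    q <- matrix(pmin(40L, pmax(2L, round(stats::rnorm(2L * n * L,
        mean = meanQ, sd = 3)))), nrow = L)
    qs <- phredEncode(lapply(seq_len(2L * n), function(i) q[, i]),
                      offset = cfg@phredOffset)
    ids <- sprintf("%s_r%06d", colnames(cnt)[j], seq_len(n))
    libs[[j]] <- list(id = ids, seq1 = s1, qual1 = qs[seq_len(n)],
                      seq2 = s2, qual2 = qs[n + seq_len(n)])
    truth[[j]] <- data.frame(read_id = ids, library = colnames(cnt)[j],
                             gene = rownames(cnt)[geneIdx],
                             origin = origin, stringsAsFactors = FALSE)
  }
  if (resampled > 0)
    warning(resampled, " fragments longer than their transcript were clamped")
  list(libraries = libs, truth = do.call(rbind, truth))
}

# iid substitution errors on a character vector of reads
injectErrors <- function(seqs, rate) {
  bases <- c("A", "C", "G", "T")
  vapply(seqs, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    hit <- which(stats::runif(length(ch)) < rate)
    if (length(hit)) {
      ch[hit] <- vapply(ch[hit], function(b)
        sample(setdiff(bases, b), 1L), character(1))
      s <- paste(ch, collapse = "")
    }
    s
  }, character(1), USE.NAMES = FALSE)
}

#' Write gene models to a GTF file
#'
#' @param geneModels a `GRanges` with a `gene_id` metadata column.
#' @param path output GTF path.
#' @return invisibly, `path`.
#' @export
writeGeneModels <- function(geneModels, path) {
  gr <- geneModels
  S4Vectors::mcols(gr)$type <- "exon"
  S4Vectors::mcols(gr)$source <- "homeoseq"
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read gene models from a GTF file
#'
#' Keeps exon records (or all records when no `type` column is present) and
#' requires a `gene_id` attribute.
#'
#' @param path GTF path.
#' @return a `GRanges` with a `gene_id` metadata column.
#' @export
readGeneModels <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  if ("type" %in% colnames(md) && any(md$type == "exon"))
    gr <- gr[md$type == "exon"]
  if (!"gene_id" %in% colnames(S4Vectors::mcols(gr)))
    stop("GTF lacks gene_id attributes")
  gr
}
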