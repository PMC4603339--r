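# Post-hoc utilities: novel-contig identity filter, N50, variant depth
# filter, mapping-ratio vs genetic-distance correlation.

#' Filter novel contigs by identity to the reference
#'
#' Contigs whose best alignment identity to the reference exceeds the
#' threshold are discarded (strict `>`, so identity exactly at the
#' threshold is kept); contigs with no hit are kept as novel.
#'
#' @param hits data.frame with `contig_id`, `best_identity` (fraction in
#'   \[0,1\], NA allowed) and optionally `has_hit` (inferred from NA
#'   identity when absent).
#' @param identityThreshold discard above this identity (default 0.70).
#' @return character vector of kept contig ids.
#' @export
filterNovelContigs <- function(hits, identityThreshold = 0.70) {
  stopifnot(identityThreshold > 0, identityThreshold < 1)
  hasHit <- if ("has_hit" %in% names(hits)) hits$has_hit
            else !is.na(hits$best_identity)
  keep <- !hasHit | hits$best_identity <= identityThreshold
  hits$contig_id[keep]
}

#' Read a 12-column blast-style tabular hit file
#'
#' Collapses an outfmt-6-style table (qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore) to one row per query
#' with its best percent identity.
#'
#' @param path TSV path (no header).
#' @param contigIds optional full contig universe; contigs without hits
#'   get `has_hit = FALSE`.
#' @return data.frame: contig_id, best_identity (fraction), has_hit.
#' @export
readBlastHits <- function(path, contigIds = NULL) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = cols, stringsAsFactors = FALSE)
  best <- tapply(tab$pident, tab$qseqid, max) / 100
  ids <- union(contigIds, names(best))
  data.frame(contig_id = ids,
             best_identity = unname(best[ids]),
             has_hit = ids %in% names(best),
             stringsAsFactors = FALSE)
}

#' Assembly N50
#'
#' The largest length L such that contigs of length >= L contain at least
#' half the total assembled bases.
#'
#' @param lengths contig lengths in bp (non-empty).
#' @return N50 in bp.
#' @examples
#' n50(c(2, 2, 2, 3, 3, 4))  # 3
#' @export
n50 <- function(lengths) {
  if (!length(lengths)) stop("empty length list")
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(as.numeric(s)) >= sum(as.numeric(s)) / 2)[1]]
}

#' Filter variants by read depth
#'
#' Keeps variants with depth strictly below the maximum (default 100).
#'
#' @param variants data.frame with a `depth` column (and any others).
#' @param maxDepth strict upper bound on depth.
#' @return the kept rows of `variants`.
#' @export
filterVariants <- function(variants, maxDepth = 100) {
  variants[variants$depth < maxDepth, , drop = FALSE]
}

#' Pearson correlation of mapping ratio against genetic distance
#'
#' @param mappingRatios per-library mapping ratios (percent).
#' @param distances per-library genetic distances (substitutions/site).
#' @return list: `r` (Pearson coefficient), `p` (two-sided t-based p
#'   value), `n`. Zero variance in either vector gives `r = NA` with a
#'   warning.
#' @export
ratioDistanceCorrelation <- function(mappingRatios, distances) {
  stopifnot(length(mappingRatios) == length(distances),
            length(mappingRatios) >= 3L)
  if (stats::sd(mappingRatios) == 0 || stats::sd(distances) == 0) {
    warning("zero variance; correlation undefined")
    return(list(r = NA_real_, p = NA_real_, n = length(distances)))
  }
  ct <- stats::cor.test(mappingRatios, distances, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(distances))
}
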