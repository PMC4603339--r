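# Fragment-per-gene counting of assigned alignments against gene models,
# and expressed-set Venn accounting across groups.

#' Count fragments per gene
#'
#' A fragment (read pair or singleton) increments exactly one gene if and
#' only if every mapped base of its primary records lies within that
#' single gene's exon union; fragments contained in no gene or compatible
#' with two or more genes are reported as unassigned. A pair counts once.
#'
#' @param records assigned alignment records (data.frame or SAM/BAM path)
#'   for one subgenome.
#' @param geneModels `GRanges` of exons with a `gene_id` metadata column.
#' @return list: `counts` (named integer vector over all gene ids),
#'   `unassigned_no_feature`, `unassigned_ambiguous`.
#' @export
countFragments <- function(records, geneModels) {
  records <- asRecords(records)
  geneIds <- unique(S4Vectors::mcols(geneModels)$gene_id)
  refLens <- attr(records, "refLengths")
  if (!is.null(refLens)) {
    bad <- setdiff(as.character(unique(
      GenomicRanges::seqnames(geneModels))), names(refLens))
    if (length(bad))
      stop("gene model contigs absent from SAM reference dictionary: ",
           paste(bad, collapse = ", "))
  }
  counts <- setNames(integer(length(geneIds)), geneIds)

  primary <- bitwAnd(records$flag, 256L) == 0L &
    bitwAnd(records$flag, 2048L) == 0L
  mapped <- bitwAnd(records$flag, 4L) == 0L
  m <- records[primary & mapped, , drop = FALSE]
  allFrag <- unique(records$qname[primary])
  if (!nrow(m))
    return(list(counts = counts, unassigned_no_feature = length(allFrag),
                unassigned_ambiguous = 0L))

  # merged exon union per gene
  grl <- GenomicRanges::reduce(S4Vectors::split(
    geneModels, S4Vectors::mcols(geneModels)$gene_id))
  exons <- unlist(grl, use.names = TRUE)
  exonGene <- names(exons)

  rr <- GenomicRanges::GRanges(
    seqnames = m$rname,
    ranges = IRanges::IRanges(start = m$pos, width = cigarRefWidth(m$cigar)))
  ov <- GenomicRanges::findOverlaps(rr, exons)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  if (!length(qh))
    return(list(counts = counts, unassigned_no_feature = length(allFrag),
                unassigned_ambiguous = 0L))
  covered <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(rr)[qh], IRanges::ranges(exons)[sh]))
  # bases of each record covered by each gene's exon union
  key <- paste0(qh, "\r", exonGene[sh])
  covTot <- rowsum(covered, key)
  kk <- strsplit(rownames(covTot), "\r", fixed = TRUE)
  recOf <- as.integer(vapply(kk, `[`, "", 1L))
  geneOf <- vapply(kk, `[`, "", 2L)
  contained <- covTot[, 1] == IRanges::width(IRanges::ranges(rr))[recOf]

  frag <- m$qname
  nRec <- table(frag)
  # (fragment, gene) pairs where the gene contains every record of the
  # fragment that it contains; compatible iff it contains all of them
  ck <- paste0(frag[recOf[contained]], "\r", geneOf[contained])
  if (length(ck)) {
    tal <- rowsum(rep(1L, length(ck)), ck)
    tk <- strsplit(rownames(tal), "\r", fixed = TRUE)
    fragOf <- vapply(tk, `[`, "", 1L)
    geneC <- vapply(tk, `[`, "", 2L)
    full <- tal[, 1] == as.integer(nRec[fragOf])
    nComp <- rowsum(as.integer(full), fragOf)
    assignedFrag <- rownames(nComp)[nComp[, 1] == 1L]
  } else {
    fragOf <- character(0); geneC <- character(0)
    full <- logical(0); assignedFrag <- character(0)
  }
  if (length(assignedFrag)) {
    gsel <- geneC[full][match(assignedFrag, fragOf[full])]
    tab <- table(gsel)
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  touched <- unique(frag[recOf])   # fragments overlapping any gene at all
  list(counts = counts,
       unassigned_no_feature = length(setdiff(allFrag, touched)),
       unassigned_ambiguous = length(setdiff(touched, assignedFrag)))
}

# reference-consumed width of simple CIGARs (M/D/N/=/X consume reference)
cigarRefWidth <- function(cigar) {
  vapply(cigar, function(cg) {
    if (cg == "*") return(0L)
    ops <- gregexpr("[0-9]+[MIDNSHP=X]", cg)[[1]]
    toks <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
    n <- as.integer(sub("[MIDNSHP=X]", "", toks))
    op <- sub("[0-9]+", "", toks)
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

#' Expressed-gene sets per group and their Venn regions
#'
#' A gene counts as expressed in a group when it has at least `minCount`
#' fragments in at least one of the group's libraries.
#'
#' @param object a [HomeologCounts-class] object with exactly three
#'   groups, or a counts matrix plus `group`.
#' @param group library group labels (ignored for `HomeologCounts`).
#' @param minCount expression threshold (default 1).
#' @return list: `sets` (per-group expressed gene ids) and `venn`, the 7
#'   region sizes named by group membership pattern (e.g. "wild",
#'   "wild&cultivar", "wild&landrace&cultivar").
#' @export
expressedTranscriptSets <- function(object, group = NULL, minCount = 1L) {
  if (is(object, "HomeologCounts")) {
    cnt <- counts(object); group <- as.character(groups(object))
  } else {
    cnt <- as.matrix(object); group <- as.character(group)
  }
  gl <- unique(group)
  if (length(gl) != 3L) stop("expected exactly three groups")
  sets <- lapply(gl, function(g)
    rownames(cnt)[rowSums(cnt[, group == g, drop = FALSE] >= minCount) > 0])
  names(sets) <- gl
  inSet <- vapply(sets, function(s) rownames(cnt) %in% s,
                  logical(nrow(cnt)))
  pat <- apply(inSet, 1L, function(z)
    paste(gl[z], collapse = "&"))
  venn <- integer(0)
  for (k in 1:3) for (cmb in utils::combn(gl, k, simplify = FALSE)) {
    nm <- paste(cmb, collapse = "&")
    venn[nm] <- sum(pat == nm)
  }
  list(sets = sets, venn = venn)
}
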