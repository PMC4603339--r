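# Negative-binomial differential expression in the classic (v1) DESeq
# style: median-of-ratios size factors, method-of-moments dispersion with
# a gamma-family mean-dispersion fit and "maximum" sharing, and the
# conditioned NB sum test. No fold-change shrinkage: ratios of group base
# means are reported as-is, including +/-Inf.

#' Median-of-ratios size factors
#'
#' `s_j = median over genes g of count_gj / geometric_mean_g`, computed
#' over genes whose geometric mean across libraries is finite and positive
#' (i.e. genes with nonzero counts in every library).
#'
#' @param counts genes x libraries count matrix.
#' @return positive numeric vector of per-library size factors.
#' @export
estimateSizeFactorsMoR <- function(counts) {
  counts <- as.matrix(counts)
  logGeo <- rowMeans(log(counts))
  use <- is.finite(logGeo)
  if (!any(use))
    stop("no gene has nonzero counts in every library; filter first")
  sf <- apply(counts, 2L, function(col)
    exp(stats::median(log(col[use]) - logGeo[use])))
  unname(sf)
}

#' Log2 fold change of group means
#'
#' `log2(meanTarget / meanRef)` with no pseudo-count: a zero target mean
#' gives `-Inf`, a zero reference mean gives `Inf`, and both zero gives
#' `NA`.
#'
#' @param meanRef,meanTarget normalised group means (>= 0).
#' @return log2 ratio (possibly +/-Inf or NA).
#' @examples
#' log2FoldChange(1093.35, 416.13)  # -1.39 to 2 dp
#' @export
log2FoldChange <- function(meanRef, meanTarget) {
  out <- log2(meanTarget / meanRef)
  out[meanRef == 0 & meanTarget == 0] <- NA_real_
  out
}

# raw method-of-moments dispersions on normalised counts, pooled across
# the two contrasted groups
rawDispersions <- function(q, groupIdx, sf) {
  xim <- mean(1 / sf)
  qbar <- rowMeans(q)
  ss <- 0; df <- 0
  for (idx in groupIdx) {
    if (length(idx) < 2L) next
    sub <- q[, idx, drop = FALSE]
    ss <- ss + rowSums((sub - rowMeans(sub))^2)
    df <- df + length(idx) - 1L
  }
  if (df == 0L) stop("need replicates to estimate dispersion")
  w <- ss / df
  (w - xim * qbar) / qbar^2
}

# gamma-family fit of dispersion ~ a0 + a1/baseMean, with lm fallback
fitDispersionTrend <- function(disp, baseMean) {
  use <- is.finite(disp) & disp > 0 & baseMean > 0
  if (sum(use) < 10L) {
    pooled <- stats::median(pmax(disp[is.finite(disp) & baseMean > 0], 1e-8))
    return(function(mu) rep(max(pooled, 1e-8), length(mu)))
  }
  d <- disp[use]; m <- baseMean[use]
  co <- tryCatch(suppressWarnings({
    fit <- stats::glm(d ~ I(1 / m), family = stats::Gamma(link = "identity"),
                      start = pmax(coef(stats::lm(d ~ I(1 / m))), 1e-4))
    stats::coef(fit)
  }), error = function(e) stats::coef(stats::lm(d ~ I(1 / m))))
  function(mu) pmax(co[1] + co[2] / mu, 1e-8)
}

#' DESeq-v1-style negative-binomial test for one contrast
#'
#' Per-gene two-sided p values from the conditioned NB sum test: given the
#' total count of a gene over both groups, the probability of group totals
#' at most as likely as those observed, under NB laws whose means come
#' from the pooled normalised mean and whose variances include the
#' per-gene dispersion. Dispersions are method-of-moments estimates
#' smoothed by a gamma-family mean-dispersion fit, sharing mode
#' "maximum" (each gene takes the larger of fitted and empirical); with
#' fewer than 10 informative genes a pooled method-of-moments value is
#' used instead of the fit.
#'
#' @param counts genes x libraries matrix, or [HomeologCounts-class].
#' @param group library group labels (ignored for `HomeologCounts`).
#' @param contrast length-2 character: (target group, reference group).
#' @param sf size factors; median-of-ratios of the full matrix by default.
#' @param dispersions optional per-gene dispersions (recycled); when
#'   supplied the estimation step is skipped.
#' @return data.frame: gene, baseMean (pooled over the contrasted
#'   libraries), meanRef, meanTarget, dispersion, log2fc, pval. Genes with
#'   zero counts in both groups get `pval = NA`.
#' @export
nbTest <- function(counts, group = NULL, contrast, sf = NULL,
                   dispersions = NULL) {
  if (is(counts, "HomeologCounts")) {
    group <- as.character(groups(counts)); counts <- counts(counts)
  }
  group <- as.character(group)
  if (!all(contrast %in% group))
    stop("contrast group missing from design: ",
         paste(setdiff(contrast, group), collapse = ", "))
  if (is.null(sf)) sf <- estimateSizeFactorsMoR(counts)
  tIdx <- which(group == contrast[1])
  rIdx <- which(group == contrast[2])
  if (length(tIdx) < 2L || length(rIdx) < 2L)
    stop("need at least two libraries per contrasted group")
  sfT <- sf[tIdx]; sfR <- sf[rIdx]
  q <- sweep(counts[, c(rIdx, tIdx), drop = FALSE], 2L,
             c(sfR, sfT), `/`)
  nR <- length(rIdx)
  baseMean <- rowMeans(q)
  meanRef <- rowMeans(q[, seq_len(nR), drop = FALSE])
  meanTarget <- rowMeans(q[, nR + seq_along(tIdx), drop = FALSE])

  if (is.null(dispersions)) {
    raw <- rawDispersions(q, list(seq_len(nR), nR + seq_along(tIdx)),
                          c(sfR, sfT))
    fitted <- fitDispersionTrend(raw, baseMean)(baseMean)
    disp <- pmax(fitted, raw, 1e-8)
  } else {
    disp <- rep_len(dispersions, nrow(counts))
  }
  disp <- pmax(disp, 1e-8)

  kR <- rowSums(counts[, rIdx, drop = FALSE])
  kT <- rowSums(counts[, tIdx, drop = FALSE])
  pval <- vapply(seq_len(nrow(counts)), function(g)
    nbSumPValue(kR[g], kT[g], baseMean[g], disp[g], sfR, sfT),
    numeric(1))
  data.frame(gene = rownames(counts) %||% as.character(seq_len(nrow(counts))),
             baseMean = baseMean, meanRef = meanRef,
             meanTarget = meanTarget, dispersion = disp,
             log2fc = log2FoldChange(meanRef, meanTarget),
             pval = pval, stringsAsFactors = FALSE, row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# conditioned NB sum test for one gene: probability, given the total, of
# group sums at most as likely as observed
nbSumPValue <- function(kR, kT, qhat, disp, sfR, sfT) {
  ks <- kR + kT
  if (ks == 0 || !is.finite(qhat) || qhat == 0) return(NA_real_)
  muR <- qhat * sum(sfR); muT <- qhat * sum(sfT)
  varR <- muR + disp * qhat^2 * sum(sfR^2)
  varT <- muT + disp * qhat^2 * sum(sfT^2)
  sizeR <- muR^2 / max(varR - muR, 1e-12)
  sizeT <- muT^2 / max(varT - muT, 1e-12)
  x <- 0:ks
  ps <- stats::dnbinom(x, mu = muR, size = sizeR) *
    stats::dnbinom(ks - x, mu = muT, size = sizeT)
  tot <- sum(ps)
  if (tot == 0) return(NA_real_)
  pobs <- ps[kR + 1L]
  min(1, sum(ps[ps <= pobs * (1 + 1e-7)]) / tot)
}

#' Benjamini-Hochberg adjusted p values
#'
#' Step-up BH with monotonicity enforcement (delegates to
#' [stats::p.adjust()]); invariant to input ordering. NAs propagate.
#'
#' @param p raw p values in \[0, 1\].
#' @return adjusted p values, same order as input.
#' @export
benjaminiHochberg <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Call differentially expressed genes
#'
#' UP: `log2fc >= lfcThreshold` and `padj <= alpha`; DOWN:
#' `log2fc <= -lfcThreshold` and `padj <= alpha`; otherwise NS. Infinite
#' fold changes pass the magnitude cut; NA fold change or padj gives NS.
#'
#' @param log2fc log2 fold changes (may contain +/-Inf).
#' @param padj BH-adjusted p values.
#' @param lfcThreshold fold-change cutoff (default 1).
#' @param alpha FDR level (default 0.1).
#' @return character vector "UP"/"DOWN"/"NS".
#' @export
callDEGs <- function(log2fc, padj, lfcThreshold = 1, alpha = 0.1) {
  call <- rep("NS", length(log2fc))
  sig <- !is.na(padj) & padj <= alpha & !is.na(log2fc)
  call[sig & log2fc >= lfcThreshold] <- "UP"
  call[sig & log2fc <= -lfcThreshold] <- "DOWN"
  call
}

#' Differential expression over both domestication contrasts
#'
#' Runs the NB test for cultivar-vs-reference and landrace-vs-reference
#' style contrasts (every non-reference group against the reference) and
#' assembles a [DEResults-class] table with per-group base means, log2
#' fold changes, raw and BH-adjusted p values and UP/DOWN/NS calls.
#'
#' @param object a [HomeologCounts-class] object.
#' @param reference reference group (default the `referenceGroup`
#'   metadata entry, else the first group level).
#' @param lfcThreshold,alpha DEG thresholds (defaults 1 and 0.1).
#' @param dispersions optional per-gene dispersions passed to [nbTest()].
#' @return a [DEResults-class] object.
#' @export
runDiffExp <- function(object, reference = NULL, lfcThreshold = 1,
                       alpha = 0.1, dispersions = NULL) {
  stopifnot(is(object, "HomeologCounts"))
  grp <- as.character(groups(object))
  if (is.null(reference))
    reference <- metadata(object)$referenceGroup %||% unique(grp)[1]
  targets <- setdiff(unique(grp), reference)
  sf <- estimateSizeFactorsMoR(counts(object))
  q <- sweep(counts(object), 2L, sf, `/`)

  out <- S4Vectors::DataFrame(row.names = rownames(counts(object)))
  out[[paste0("baseMean_", reference)]] <-
    rowMeans(q[, grp == reference, drop = FALSE])
  res <- list()
  for (tg in targets) {
    r <- nbTest(counts(object), grp, contrast = c(tg, reference), sf = sf,
                dispersions = dispersions)
    padj <- benjaminiHochberg(r$pval)
    out[[paste0("baseMean_", tg)]] <- rowMeans(q[, grp == tg, drop = FALSE])
    out[[paste0("log2fc_", tg)]] <- r$log2fc
    out[[paste0("pval_", tg)]] <- r$pval
    out[[paste0("padj_", tg)]] <- padj
    out[[paste0("call_", tg)]] <- callDEGs(r$log2fc, padj, lfcThreshold,
                                           alpha)
    res[[tg]] <- r
  }
  out <- new("DEResults", out)
  metadata(out) <- list(reference = reference, targets = targets,
                        lfcThreshold = lfcThreshold, alpha = alpha,
                        sizeFactors = sf)
  out
}

#' Direction-consistent intersection of two DEG contrasts
#'
#' The domesticated-vs-wild candidate set: genes called in both contrasts
#' with the same direction, plus the Venn region sizes of the two DEG
#' sets.
#'
#' @param callsX,callsY named character vectors of "UP"/"DOWN"/"NS" calls
#'   (same gene universe), e.g. the `call_*` columns of [runDiffExp()].
#' @return list: `genes` (named vector of UP/DOWN for the intersection),
#'   `venn` (sizes: onlyX, onlyY, both_consistent, both_conflicting).
#' @export
domesticatedVsWild <- function(callsX, callsY) {
  stopifnot(length(callsX) == length(callsY))
  degX <- callsX != "NS"; degY <- callsY != "NS"
  both <- degX & degY
  consistent <- both & callsX == callsY
  genes <- callsX[consistent]
  list(genes = genes,
       venn = c(onlyX = sum(degX & !degY), onlyY = sum(degY & !degX),
                both_consistent = sum(consistent),
                both_conflicting = sum(both & callsX != callsY)))
}
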