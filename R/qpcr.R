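# qPCR arithmetic: standard-curve amplification efficiency and
# efficiency-corrected relative quantification (delta-delta-Ct).

#' Fit a qPCR standard curve and amplification efficiency
#'
#' Least-squares line of Ct against log10 relative input from a serial
#' dilution; the per-cycle amplification efficiency is
#' `E = 10^(-1/slope)` (E = 2 means perfect doubling, 100%).
#'
#' @param dilutionLog10 log10 of relative template input (>= 3 distinct
#'   points).
#' @param ct observed Ct values.
#' @param gene,group optional labels stored on the result.
#' @return list: gene, group, slope, intercept, r_squared, efficiency,
#'   efficiency_percent (`(E - 1) * 100`), valid (FALSE when slope >= 0).
#' @examples
#' fitStandardCurve(c(0, -1, -2), c(20, 23.3219, 26.6439))$efficiency
#' @export
fitStandardCurve <- function(dilutionLog10, ct, gene = NA_character_,
                             group = NA_character_) {
  stopifnot(length(dilutionLog10) == length(ct))
  if (length(unique(dilutionLog10)) < 3L)
    stop("need at least three distinct dilution points")
  fit <- stats::lm(ct ~ dilutionLog10)
  slope <- unname(stats::coef(fit)[2])
  eff <- 10^(-1 / slope)
  valid <- slope < 0
  if (!valid) warning("non-negative slope; curve flagged invalid")
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((ct - mean(ct))^2)
  list(gene = gene, group = group, slope = slope,
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2,
       efficiency = eff, efficiency_percent = (eff - 1) * 100,
       valid = valid)
}

#' Efficiency-corrected relative quantification
#'
#' `RQ = E_target^(-dCt_target) / E_endo^(-dCt_endo)` where
#' `dCt = mean Ct(treatment) - mean Ct(control)` and replicate Cts are
#' averaged arithmetically first. With both efficiencies equal to 2 this
#' is exactly the 2^(-ddCt) method, which is also the fallback when no
#' standard curves are supplied.
#'
#' @param ct data.frame with columns `gene`, `group`, `replicate`, `ct`.
#' @param targetGene gene to quantify.
#' @param treatmentGroup,controlGroup group labels compared.
#' @param endogenousGene normaliser gene (default "Ubiquitin").
#' @param curves optional list of standard curves (from
#'   [fitStandardCurve()]); the curve whose `gene` matches is used, with
#'   per-group curves (`group` matching the treatment group) preferred.
#'   Missing curves fall back to E = 2.
#' @return list: rq, dct_target, dct_endo, e_target, e_endo.
#' @export
relativeQuantification <- function(ct, targetGene, treatmentGroup,
                                   controlGroup,
                                   endogenousGene = "Ubiquitin",
                                   curves = NULL) {
  meanCt <- function(gene, grp) {
    v <- ct$ct[ct$gene == gene & ct$group == grp]
    if (!length(v)) stop("missing Ct for ", gene, " in ", grp)
    mean(v)
  }
  if (!endogenousGene %in% ct$gene)
    stop("endogenous gene '", endogenousGene, "' absent from Ct table")
  eff <- function(gene, grp) {
    if (is.null(curves)) return(2)
    hit <- Filter(function(cv) identical(cv$gene, gene) &&
                    identical(cv$group, grp), curves)
    if (!length(hit))
      hit <- Filter(function(cv) identical(cv$gene, gene) &&
                      is.na(cv$group), curves)
    if (!length(hit)) return(2)
    hit[[1]]$efficiency
  }
  dctT <- meanCt(targetGene, treatmentGroup) -
    meanCt(targetGene, controlGroup)
  dctE <- meanCt(endogenousGene, treatmentGroup) -
    meanCt(endogenousGene, controlGroup)
  eT <- eff(targetGene, treatmentGroup)
  eE <- eff(endogenousGene, treatmentGroup)
  list(rq = eT^(-dctT) / eE^(-dctE),
       dct_target = dctT, dct_endo = dctE,
       e_target = eT, e_endo = eE)
}
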