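# Independent oracles used by the tests. These deliberately re-derive
# expectations by brute force / direct formulas, not by calling the code
# under test.

# naive rule-by-rule arbitration interpreter: compare (status rank,
# uniqueness, MQS) as a lexicographic tuple
oracleArbitrate <- function(evA, evB) {
  rank <- c(UNMAPPED = 0, SINGLETON = 1, PAIR = 2)
  a <- c(rank[[evA$status]], as.numeric(isTRUE(evA$unique)), evA$mqs)
  b <- c(rank[[evB$status]], as.numeric(isTRUE(evB$unique)), evB$mqs)
  if (a[1] == 0 && b[1] == 0) return("UNMAPPED")
  if (a[1] == 0) return("ASSIGN_B")
  if (b[1] == 0) return("ASSIGN_A")
  d <- which(a != b)
  if (!length(d)) return("DISCARD_TIE")
  if (a[d[1]] > b[d[1]]) "ASSIGN_A" else "ASSIGN_B"
}

# direct re-implementation of the sliding-window scan: index of the first
# window (start position) whose mean quality is below the threshold, 0 if
# none
oracleFirstFailingWindow <- function(q, w, thr) {
  if (length(q) < w) return(0L)
  for (i in seq_len(length(q) - w + 1L))
    if (mean(q[i:(i + w - 1L)]) < thr) return(i)
  0L
}

# brute-force median-of-ratios
oracleSizeFactors <- function(m) {
  geo <- apply(m, 1, function(r) exp(mean(log(r))))
  ok <- is.finite(geo) & geo > 0
  apply(m, 2, function(col) median(col[ok] / geo[ok]))
}

# hand step-up BH
oracleBH <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# brute-force three-set Venn region sizes keyed by membership pattern
oracleVenn <- function(sets) {
  gl <- names(sets)
  all <- unique(unlist(sets))
  pat <- vapply(all, function(g)
    paste(gl[vapply(sets, function(s) g %in% s, logical(1))],
          collapse = "&"), character(1))
  out <- integer(0)
  for (k in 1:3) for (cmb in combn(gl, k, simplify = FALSE)) {
    nm <- paste(cmb, collapse = "&")
    out[nm] <- sum(pat == nm)
  }
  out
}

# textbook Pearson r and two-sided t-based p
oraclePearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(t), df = n - 2))
}

# evidence row constructor for arbitration tests
ev <- function(status, mqs = 0, unique = FALSE, id = "r1", sg = "A") {
  list(read_id = id, subgenome = sg, status = status, mqs = mqs,
       unique = unique)
}

# random read with quality string, for trim property tests
randomRead <- function(len, qRange = c(2, 40), offset = 33L) {
  list(seq = paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = ""),
       qual = intToUtf8(sample(seq(qRange[1], qRange[2]), len, TRUE) +
                          offset))
}

extfile <- function(f) system.file("extdata", f, package = "homeoseq")
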