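test_that("size factors: identical libraries get factor 1", {
  m <- matrix(rep(c(5L, 10L, 20L), 3), ncol = 3)
  expect_equal(estimateSizeFactorsMoR(m), c(1, 1, 1))
})

test_that("size factors: a doubled library splits the scale symmetrically", {
  set.seed(61)
  base <- rpois(50, 50) + 1L
  m <- cbind(base, 2L * base)
  sf <- estimateSizeFactorsMoR(m)
  expect_equal(sf, c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
})

test_that("size factors match a brute-force median-of-ratios oracle", {
  # odd gene count: the ratio-space and log-space medians coincide
  # exactly, so the oracle is convention-free
  set.seed(62)
  m <- matrix(rpois(51 * 4, 30) + 1L, nrow = 51, ncol = 4)
  expect_equal(estimateSizeFactorsMoR(m), unname(oracleSizeFactors(m)),
               tolerance = 1e-12)
})

test_that("size factors agree with the DESeq2 estimator", {
  skip_if_not_installed("DESeq2")
  set.seed(63)
  m <- matrix(rnbinom(400, mu = 80, size = 5), nrow = 100, ncol = 4)
  expect_equal(estimateSizeFactorsMoR(m),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-10)
})

test_that("a matrix with no all-positive gene is rejected", {
  m <- matrix(c(0L, 5L, 3L, 0L), nrow = 2)
  expect_error(estimateSizeFactorsMoR(m), "filter")
})

test_that("log2 fold changes reproduce printed worked examples, including infinities", {
  expect_equal(roundHalfUp(log2FoldChange(1093.35, 416.13), 2), -1.39)
  expect_equal(roundHalfUp(log2FoldChange(42.47, 1189.91), 2), 4.81)
  expect_identical(log2FoldChange(177.41, 0), -Inf)
  expect_identical(log2FoldChange(0, 53.86), Inf)
  expect_equal(log2FoldChange(7, 7), 0)
  expect_true(is.na(log2FoldChange(0, 0)))
})

test_that("log2 fold change is antisymmetric when finite", {
  set.seed(64)
  a <- runif(50, 1, 1000); b <- runif(50, 1, 1000)
  expect_equal(log2FoldChange(a, b), -log2FoldChange(b, a))
})

test_that("BH adjustment matches hand-computed step-up values and p.adjust invariants", {
  expect_equal(benjaminiHochberg(0.04), 0.04)           # m = 1 identity
  expect_equal(benjaminiHochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))                            # hand step-up
  expect_equal(benjaminiHochberg(rep(1, 5)), rep(1, 5))
  set.seed(65)
  p <- runif(100)
  expect_equal(benjaminiHochberg(p), oracleBH(p))
  o <- sample(100)
  expect_equal(benjaminiHochberg(p[o]), benjaminiHochberg(p)[o])
  expect_error(benjaminiHochberg(c(0.5, 1.2)), "\\[0, 1\\]")
  adj <- benjaminiHochberg(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
})

test_that("DEG calls respect the fold-change and FDR thresholds", {
  expect_equal(callDEGs(0.9, 0.001), "NS")      # below |log2FC| cutoff
  expect_equal(callDEGs(1, 0.1), "UP")          # boundary passes
  expect_equal(callDEGs(-Inf, 0.02), "DOWN")    # -Inf passes magnitude cut
  expect_equal(callDEGs(Inf, 0.02), "UP")
  expect_equal(callDEGs(2.5, 0.2), "NS")        # fails FDR
  expect_equal(callDEGs(NA, 0.01), "NS")
})

test_that("the NB test is calibrated on null data with known dispersion", {
  set.seed(66)
  n <- 2000
  mu <- rlnorm(n, log(150), 1)
  cnt <- sapply(1:4, function(j) rnbinom(n, mu = mu, size = 1 / 0.1))
  dimnames(cnt) <- list(paste0("g", 1:n), c("w1", "w2", "c1", "c2"))
  grp <- c("wild", "wild", "cultivar", "cultivar")
  r <- nbTest(cnt, grp, contrast = c("cultivar", "wild"),
              dispersions = 0.1)
  rate <- mean(r$pval < 0.05, na.rm = TRUE)
  ciHalf <- 2.576 * sqrt(0.05 * 0.95 / n)   # binomial 99% CI of nominal
  expect_lt(abs(rate - 0.05), ciHalf)
})

test_that("the estimated-dispersion path is not anticonservative", {
  set.seed(67)
  n <- 2000
  mu <- rlnorm(n, log(150), 1)
  cnt <- sapply(1:4, function(j) rnbinom(n, mu = mu, size = 1 / 0.1))
  dimnames(cnt) <- list(paste0("g", 1:n), c("w1", "w2", "c1", "c2"))
  r <- nbTest(cnt, c("wild", "wild", "cultivar", "cultivar"),
              contrast = c("cultivar", "wild"))
  rate <- mean(r$pval < 0.05, na.rm = TRUE)
  expect_lt(rate, 0.05 + 2.576 * sqrt(0.05 * 0.95 / n))
})

test_that("planted four-fold changes at mean 200 are detected with high power", {
  set.seed(68)
  n <- 2000; nde <- 100
  mu <- rlnorm(n, log(150), 1); mu[1:nde] <- 200
  fc <- rep(1, n); fc[1:nde] <- 4
  cnt <- cbind(sapply(1:2, function(j) rnbinom(n, mu = mu, size = 20)),
               sapply(1:2, function(j) rnbinom(n, mu = mu * fc, size = 20)))
  dimnames(cnt) <- list(paste0("g", 1:n), c("w1", "w2", "c1", "c2"))
  r <- nbTest(cnt, c("wild", "wild", "cultivar", "cultivar"),
              contrast = c("cultivar", "wild"))
  expect_gte(mean(r$pval[1:nde] < 0.01, na.rm = TRUE), 0.8)
})

test_that("an all-zero gene is never significant", {
  cnt <- rbind(g1 = c(0L, 0L, 0L, 0L), g2 = c(10L, 12L, 11L, 9L))
  r <- nbTest(cnt, c("wild", "wild", "cultivar", "cultivar"),
              contrast = c("cultivar", "wild"), dispersions = 0.1)
  expect_true(is.na(r$pval[1]))
  expect_equal(callDEGs(r$log2fc, benjaminiHochberg(r$pval))[1], "NS")
})

test_that("p values are invariant to rescaling one library on a proportional fixture", {
  # dispersion-0 fixture: counts exactly proportional to size factors
  mu <- c(20, 50, 100, 400, 1000)
  cnt <- outer(mu, c(1, 1, 1, 1))
  dimnames(cnt) <- list(paste0("g", 1:5), c("w1", "w2", "c1", "c2"))
  grp <- c("wild", "wild", "cultivar", "cultivar")
  r1 <- nbTest(cnt, grp, contrast = c("cultivar", "wild"),
               dispersions = 1e-8)
  cnt2 <- cnt; cnt2[, 1] <- cnt2[, 1] * 3L
  r2 <- nbTest(cnt2, grp, contrast = c("cultivar", "wild"),
               dispersions = 1e-8)
  expect_equal(r1$pval, r2$pval, tolerance = 1e-8)
  expect_equal(r1$log2fc, r2$log2fc, tolerance = 1e-8)
})

test_that("planted effect sizes are recovered within a quarter log2 unit", {
  up <- setNames(rep(2, 50), sprintf("g%04d", 1:50))
  dn <- setNames(rep(2, 50), sprintf("g%04d", 51:100))
  cfg <- simConfig(nGenes = 1000, plantedUp = up, plantedDown = dn,
                   dispersion = 0.05, seed = 69)
  hc <- simulateCounts(cfg, baseMeans = rep(150, 1000))
  de <- runDiffExp(hc)
  lfc <- de$log2fc_cultivar
  names(lfc) <- rownames(de)
  expect_lt(abs(median(lfc[names(up)]) - 2), 0.25)
  expect_lt(abs(median(lfc[names(dn)]) + 2), 0.25)
})

test_that("realized FDR of DEG calls stays near the nominal 10% level", {
  up <- setNames(rep(2, 100), sprintf("g%04d", 1:100))
  dn <- setNames(rep(2, 100), sprintf("g%04d", 101:200))
  cfg <- simConfig(nGenes = 2000, plantedUp = up, plantedDown = dn,
                   dispersion = 0.05, seed = 70)
  hc <- simulateCounts(cfg)
  de <- runDiffExp(hc)
  truth <- S4Vectors::metadata(hc)$deStatus
  for (tg in S4Vectors::metadata(de)$targets) {
    calls <- de[[paste0("call_", tg)]]
    called <- rownames(de)[calls != "NS"]
    expect_gt(length(called), 100)
    fdr <- mean(truth[called] == "null")
    expect_lte(fdr, 0.1 + 2.576 * sqrt(0.1 * 0.9 / length(called)))
  }
})

test_that("the domesticated-vs-wild intersection keeps only direction-consistent genes", {
  x <- c(g1 = "UP", g2 = "UP", g3 = "DOWN", g4 = "NS", g5 = "DOWN")
  y <- c(g1 = "UP", g2 = "DOWN", g3 = "DOWN", g4 = "UP", g5 = "NS")
  out <- domesticatedVsWild(x, y)
  expect_identical(names(out$genes), c("g1", "g3"))
  expect_identical(unname(out$genes), c("UP", "DOWN"))
  expect_equal(unname(out$venn["both_conflicting"]), 1)
  expect_equal(unname(out$venn["onlyX"]), 1)
  expect_equal(unname(out$venn["onlyY"]), 1)
  # set-algebra oracle on random calls
  set.seed(71)
  rx <- setNames(sample(c("UP", "DOWN", "NS"), 200, TRUE),
                 paste0("g", 1:200))
  ry <- setNames(sample(c("UP", "DOWN", "NS"), 200, TRUE),
                 paste0("g", 1:200))
  o <- domesticatedVsWild(rx, ry)
  expect_equal(length(o$genes),
               sum(rx != "NS" & ry != "NS" & rx == ry))
  expect_equal(unname(o$venn["onlyX"]), sum(rx != "NS" & ry == "NS"))
})
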