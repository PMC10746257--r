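mkRna <- function(counts, condition, lengths = rep(1000, nrow(counts))) {
  rownames(counts) <- sprintf("g%03d", seq_len(nrow(counts)))
  omicsExperiment(counts, condition,
    stats::setNames(stats::ave(seq_along(condition), condition,
      FUN = seq_along), NULL), kind = "rna", lengths = lengths)
}

test_that("TPM matches the definition and its conservation law", {
  m <- matrix(c(10, 40), 2, 1)
  oe <- mkRna(m, "Ctrl", lengths = c(1000, 2000))
  tpm <- tpmNormalize(oe)
  expect_equal(unname(tpm[, 1]), c(1e6 / 3, 2e6 / 3), tolerance = 1e-9)

  set.seed(1)
  m2 <- matrix(rpois(60, 40), 10, 6)
  oe2 <- mkRna(m2, rep(c("Ctrl", "HS1"), each = 3),
    lengths = sample(500:2000, 10))
  tpm2 <- tpmNormalize(oe2)
  expect_equal(unname(colSums(tpm2)), rep(1e6, 6), tolerance = 1e-6)

  ## doubling a sample's counts leaves its TPM unchanged
  m3 <- m2
  m3[, 2] <- m3[, 2] * 2
  expect_equal(tpmNormalize(mkRna(m3, rep(c("Ctrl", "HS1"), each = 3),
    lengths = geneLengths(oe2)))[, 2], tpm2[, 2])

  m4 <- m2
  m4[, 1] <- 0
  expect_warning(tpm4 <- tpmNormalize(mkRna(m4,
    rep(c("Ctrl", "HS1"), each = 3), lengths = geneLengths(oe2))),
    "all-zero")
  expect_true(all(tpm4[, 1] == 0))
})

test_that("median-of-ratios size factors have their closed forms", {
  set.seed(2)
  a <- rpois(50, 100) + 1
  m <- cbind(s1 = a, s2 = 2 * a)
  expect_equal(unname(sizeFactors(m)), c(1 / sqrt(2), sqrt(2)))
  expect_equal(unname(sizeFactors(cbind(a, a, a))), rep(1, 3))
  expect_equal(unname(sizeFactors(cbind(only = a))), 1)
  expect_error(sizeFactors(cbind(c(0, 1), c(1, 0))), "pseudocount")
})

test_that("size factors agree with the DESeq2 reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(3)
  m <- matrix(rnbinom(300, mu = 150, size = 5), 50, 6)
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  ref <- ref / exp(mean(log(ref)))
  expect_equal(unname(sizeFactors(m)), unname(ref), tolerance = 1e-12)
})

test_that("identical groups give log2FC 0 and p 1; groups swap antisymmetrically", {
  set.seed(4)
  base <- rpois(30, 80)
  counts <- cbind(base, base, base, base, base, base, base, base)
  oe <- mkRna(counts, rep(c("Ctrl", "HS1"), each = 4))
  de <- rnaDeTest(oe, "HS1")
  expect_true(all(de$log2FC == 0))
  expect_true(all(de$p == 1))

  set.seed(5)
  counts2 <- matrix(rnbinom(240, mu = 100, size = 10), 30, 8)
  oeA <- mkRna(counts2, rep(c("Ctrl", "HS1"), each = 4))
  oeB <- mkRna(counts2[, c(5:8, 1:4)], rep(c("Ctrl", "HS1"), each = 4))
  deA <- rnaDeTest(oeA, "HS1")
  deB <- rnaDeTest(oeB, "HS1")
  expect_equal(deA$log2FC, -deB$log2FC)
  expect_equal(deA$p, deB$p)
})

test_that("genes absent from both conditions are omitted", {
  counts <- rbind(c(5, 6, 7, 8, 9, 10, 11, 12), rep(0, 8))
  oe <- mkRna(counts, rep(c("Ctrl", "HS1"), each = 4))
  de <- rnaDeTest(oe, "HS1")
  expect_identical(nrow(de), 1L)
})

test_that("protein test: identical groups are null, moderation matches limma", {
  set.seed(6)
  x <- matrix(2^rnorm(400, 10, 1), 50, 8)
  rownames(x) <- sprintf("p%02d", 1:50)
  same <- x[, c(1:4, 1:4)]
  colnames(same) <- paste0("s", 1:8)
  oe <- omicsExperiment(same, rep(c("Ctrl", "HS1"), each = 4), rep(1:4, 2),
    kind = "protein")
  de <- proteinDeTest(oe, "HS1")
  expect_true(all(abs(de$log2FC) < 1e-12))
  expect_true(all(de$p > 1 - 1e-9))

  skip_if_not_installed("limma")
  oe2 <- omicsExperiment(x, rep(c("Ctrl", "HS1"), each = 4), rep(1:4, 2),
    kind = "protein")
  de2 <- proteinDeTest(oe2, "HS1")
  ## same upper-quartile normalization, then limma's squeezeVar as the
  ## reference for the prior and posterior variances
  q75 <- apply(x, 2, stats::quantile, 0.75)
  lx <- log2(sweep(x, 2, exp(mean(log(q75))) / q75, "*"))
  grp <- rep(c(0, 1), each = 4)
  s2 <- apply(lx, 1, function(v) {
    (sum((v[1:4] - mean(v[1:4]))^2) + sum((v[5:8] - mean(v[5:8]))^2)) / 6
  })
  sq <- limma::squeezeVar(s2, df = 6)
  expect_equal(attr(de2, "d0"), sq$df.prior, tolerance = 0.05)
  expect_equal(attr(de2, "s0sq"), sq$var.prior, tolerance = 0.01)
  tref <- (rowMeans(lx[, 5:8]) - rowMeans(lx[, 1:4])) /
    sqrt(sq$var.post * (1 / 4 + 1 / 4))
  pref <- 2 * stats::pt(-abs(tref), df = sq$df.prior + 6)
  expect_equal(de2$p, unname(pref), tolerance = 0.02)
})

test_that("infinite prior df reduces the protein test to a pooled-variance t", {
  ## equal sample variances for every gene force d0 -> Inf
  base <- c(-1.5, -0.5, 0.5, 1.5)
  x <- 2^(10 + rbind(
    c(base, base + 2), c(base + 1, base), c(base, base - 1),
    c(base + 3, base), c(base, base + 0.5), c(base - 2, base),
    c(base, base), c(base + 1.2, base), c(base, base + 0.1),
    c(base, base - 0.7), c(base + 4, base), c(base, base + 1)
  ))
  rownames(x) <- sprintf("p%02d", seq_len(nrow(x)))
  oe <- omicsExperiment(x, rep(c("Ctrl", "HS1"), each = 4), rep(1:4, 2),
    kind = "protein")
  de <- proteinDeTest(oe, "HS1")
  expect_true(!is.finite(attr(de, "d0")) || attr(de, "d0") > 1e4)
  ## statistic equals an ordinary t with the common pooled variance
  q75 <- apply(x, 2, stats::quantile, 0.75)
  lx <- log2(sweep(x, 2, exp(mean(log(q75))) / q75, "*"))
  s0 <- attr(de, "s0sq")
  tref <- (rowMeans(lx[, 5:8]) - rowMeans(lx[, 1:4])) / sqrt(s0 / 2)
  pref <- 2 * stats::pnorm(-abs(tref)) # df -> Inf
  expect_equal(de$p, unname(pref), tolerance = 1e-4)
})

test_that("BH adjustment matches the step-up oracle and its edge cases", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bhAdjust(0.2), 0.2)
  expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
  expect_error(bhAdjust(c(0.5, 1.2)), "0, 1")
  for (seed in 1:5) {
    set.seed(seed)
    p <- runif(40)^2
    expect_equal(bhAdjust(p), bruteBH(p))
  }
})

test_that("regulation grouping applies the fold-change thresholds, boundaries included", {
  expect_identical(
    classifyRegulation(c(5.4, 0.5, -1.0, 1.0, -0.5, 0.5, 2),
      c(1e-6, 0.2, 0.01, 0.04, 0.01, 0.049, NA), "rna"),
    c("strong_up", "ns", "strong_down", "strong_up", "down", "up", "ns"))
  expect_identical(
    classifyRegulation(c(0.2, -0.1, 0.4), c(0.01, 0.01, 0.2), "protein"),
    c("up", "down", "ns"))
  expect_error(classifyRegulation(1, 1.5, "rna"))
})

test_that("deAnalysis assembles contrasts with per-contrast BH and groups", {
  set.seed(8)
  counts <- matrix(rnbinom(50 * 12, mu = 120, size = 8), 50, 12)
  oe <- mkRna(counts, rep(c("Ctrl", "HS1", "CS1"), each = 4))
  de <- deAnalysis(oe)
  expect_setequal(unique(de$contrast), c("HS1_vs_Ctrl", "CS1_vs_Ctrl"))
  sub <- de[de$contrast == "HS1_vs_Ctrl", ]
  expect_equal(sub$padj, bhAdjust(sub$p))
  expect_true(all(sub$padj >= sub$p))
  expect_identical(sub$group,
    classifyRegulation(sub$log2FC, sub$padj, "rna"))
})
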