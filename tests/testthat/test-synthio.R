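## one small simulated study reused across tests in this file
cfgSmall <- simConfig(seed = 3, nGenes = 50L, contigLength = 120000L)
simSmall <- makeGenomeAnnotation(cfgSmall)

test_that("simulation is byte-identical under the same seed and config", {
  sim2 <- makeGenomeAnnotation(simConfig(seed = 3, nGenes = 50L,
    contigLength = 120000L))
  expect_identical(as.character(simSmall$genome), as.character(sim2$genome))
  expect_identical(simSmall$truth$genes, sim2$truth$genes)
  expect_identical(simSmall$truth$rna_l2fc, sim2$truth$rna_l2fc)
  tr1 <- simulateTermseq(cfgSmall, simSmall$truth)
  tr2 <- simulateTermseq(cfgSmall, sim2$truth)
  expect_identical(trackCounts(tr1[[1]]$plus), trackCounts(tr2[[1]]$plus))
  om1 <- simulateOmics(cfgSmall, simSmall$truth)
  om2 <- simulateOmics(cfgSmall, sim2$truth)
  expect_identical(SummarizedExperiment::assay(om1$rna),
    SummarizedExperiment::assay(om2$rna))
})

test_that("leaderless fraction matches the truth table and the config", {
  tg <- simSmall$truth$genes
  expect_identical(sum(tg$utr5_len == 0),
    sum(simSmall$genes$utr5_len == 0))
  cfgL <- simConfig(seed = 11, nGenes = 400L, contigLength = 900000L,
    leaderlessFraction = 0.15)
  tgl <- makeGenomeAnnotation(cfgL)$truth$genes
  expect_gt(mean(tgl$utr5_len == 0), 0.09)
  expect_lt(mean(tgl$utr5_len == 0), 0.22)
})

test_that("planted promoters appear in the -50..+10 window around the TSS", {
  tg <- simSmall$truth$genes
  for (i in which(tg$promoter)) {
    win <- senseWindow(simSmall$genome, tg$contig[i], tg$tss[i],
      tg$strand[i], -50L, 10L)
    inst <- senseWindow(simSmall$genome, tg$contig[i], tg$tss[i],
      tg$strand[i], -38L, -26L)
    expect_true(grepl(inst, win, fixed = TRUE))
    expect_match(inst, "^[GC][AT]AAA..TTT[AT][AT][AT]$")
  }
})

test_that("planted poly(U) stretches are U-rich on the coding strand", {
  tg <- simSmall$truth$genes
  for (i in which(tg$polyU)) {
    s <- senseWindow(simSmall$genome, tg$contig[i], tg$primary_pos[i],
      tg$strand[i], -13L, 2L)
    expect_gte(sum(strsplit(s, "")[[1]] == "T"), 10)
  }
})

test_that("gene layout respects spacing and feature-coordinate invariants", {
  tg <- simSmall$truth$genes
  o <- order(tg$start)
  expect_true(all(tg$start[o][-1] - tg$end[o][-nrow(tg)] > 400))
  expect_true(all(tg$primary_pos >= 1 & tg$primary_pos <= cfgSmall@contigLength))
  expect_true(all(tg$cluster %in% 0:cfgSmall@kTrue))
  dirv <- ifelse(tg$strand == "+", 1L, -1L)
  bnd <- ifelse(tg$strand == "+", tg$end, tg$start)
  expect_identical(as.integer((tg$primary_pos - bnd) * dirv), tg$utr3_len)
  expect_true(all(tg$utr3_len >= 1))
})

test_that("noise-free Term-seq places every read exactly at the true ends", {
  cfg0 <- simConfig(seed = 4, nGenes = 30L, contigLength = 80000L,
    jitterSd = 0, backgroundRate = 0)
  sim0 <- makeGenomeAnnotation(cfg0)
  tracks <- simulateTermseq(cfg0, sim0$truth)
  tg <- sim0$truth$genes
  truthPos <- list(
    "+" = c(tg$primary_pos, tg$secondary_pos, tg$internal_pos)[
      rep(tg$strand, 3) == "+"],
    "-" = c(tg$primary_pos, tg$secondary_pos, tg$internal_pos)[
      rep(tg$strand, 3) == "-"]
  )
  for (tr in tracks) {
    expect_true(all(trackPositions(tr$plus) %in% truthPos[["+"]]))
    expect_true(all(trackPositions(tr$minus) %in% truthPos[["-"]]))
  }
})

test_that("background end reads appear at roughly the configured rate", {
  cfgB <- simConfig(seed = 6, nGenes = 5L, contigLength = 100000L,
    backgroundRate = 1e-3, endHeightMin = 0, endHeightMeanLog = log(1e-9),
    secondaryFraction = 0, internalFraction = 0)
  simB <- makeGenomeAnnotation(cfgB)
  tracks <- simulateTermseq(cfgB, simB$truth)
  perRep <- vapply(tracks, function(tr)
    sum(trackCounts(tr$plus)) + sum(trackCounts(tr$minus)), numeric(1))
  ## ~ Poisson(2 strands x 1e-3 x 1e5 = 200) per replicate, plus a
  ## negligible planted contribution
  expect_true(all(perRep > 120 & perRep < 290))
})

test_that("degenerate omics configurations hit their closed-form limits", {
  cfg0 <- simConfig(seed = 5, nGenes = 40L, contigLength = 100000L,
    pi0 = 1, kTrue = 0L)
  sim0 <- makeGenomeAnnotation(cfg0)
  expect_true(all(sim0$truth$rna_l2fc == 0))
  expect_true(all(sim0$truth$protein_l2fc == 0))

  cfg1 <- simConfig(seed = 5, nGenes = 40L, contigLength = 100000L,
    rnaProteinRho = 1)
  sim1 <- makeGenomeAnnotation(cfg1)
  expect_equal(sim1$truth$protein_l2fc, sim1$truth$rna_l2fc)
})

test_that("planted RNA and protein effects correlate at the target rho", {
  cfgR <- simConfig(seed = 8, nGenes = 2000L, contigLength = 4000000L)
  simR <- makeGenomeAnnotation(cfgR)
  stress <- setdiff(colnames(simR$truth$rna_l2fc), "Ctrl")
  r <- stats::cor(as.vector(simR$truth$rna_l2fc[, stress]),
    as.vector(simR$truth$protein_l2fc[, stress]))
  expect_lt(abs(r - cfgR@rnaProteinRho), 0.1)
})

test_that("long reads obey the readthrough and jitter limits", {
  tg <- simSmall$truth$genes
  sameStrandAdj <- NULL
  o <- order(tg$start)
  for (k in seq_len(nrow(tg) - 1)) {
    i <- o[k]; j <- o[k + 1]
    if (tg$strand[i] == "+" && tg$strand[j] == "+") {
      sameStrandAdj <- c(i, j); break
    }
  }
  skip_if(is.null(sameStrandAdj), "no same-strand adjacent pair in fixture")
  up <- tg$gene_id[sameStrandAdj[1]]
  down <- tg$gene_id[sameStrandAdj[2]]

  rd0 <- simulateLongreads(cfgSmall, simSmall$truth, nReads = 10L,
    endJitter = 0)
  ## jitter 0, readthrough 0: boundaries exactly TSS / primary end
  for (i in seq_len(nrow(tg))) {
    sub <- rd0[rd0$strand == tg$strand[i] &
      rd0$start == pmin(tg$tss[i], tg$primary_pos[i]) &
      rd0$end == pmax(tg$tss[i], tg$primary_pos[i]), ]
    expect_gte(nrow(sub), 10)
  }
  ov <- function(rd, g) {
    gi <- match(g, tg$gene_id)
    rd$start <= tg$end[gi] & rd$end >= tg$start[gi]
  }
  expect_identical(sum(ov(rd0, up) & ov(rd0, down)), 0L)

  pairs <- data.frame(up = up, down = down, readthrough = 1)
  rd1 <- simulateLongreads(cfgSmall, simSmall$truth, operonPairs = pairs,
    nReads = 10L, endJitter = 0)
  both <- ov(rd1, up) & ov(rd1, down)
  expect_identical(sum(both), 10L)
})

test_that("simulation files round-trip through the core readers", {
  dir <- withr::local_tempdir()
  tracks <- simulateTermseq(cfgSmall, simSmall$truth)
  omics <- simulateOmics(cfgSmall, simSmall$truth)
  files <- writeSimulation(simSmall, tracks, omics, dir)
  g <- readGenomeFasta(files[["genome"]])
  expect_identical(as.character(g), as.character(simSmall$genome))
  genes <- readGff3Genes(files[["genes"]])
  expect_identical(genes$gene_id, simSmall$genes$gene_id)
  expect_identical(genes$tss, simSmall$genes$tss)
  tr <- readEndTrack(files[["termseq_rep1_plus"]],
    stats::setNames(Biostrings::width(g), names(g)), "+",
    libraryTotal = libraryTotal(tracks[[1]]$plus))
  expect_identical(trackPositions(tr), trackPositions(tracks[[1]]$plus))
  expect_equal(trackCounts(tr), trackCounts(tracks[[1]]$plus))
})
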