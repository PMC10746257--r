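test_that("consensus-seeded PWM probabilities and scores follow the definition", {
  p1 <- pwmFromConsensus("A")
  expect_equal(pwmScores(p1)["A", 1], log2(0.9 / 0.25))
  expect_equal(pwmScores(p1)["C", 1], log2((0.1 / 3) / 0.25))

  pw <- pwmFromConsensus("W")
  expect_equal(pw@probs["A", 1], 0.45)
  expect_equal(pw@probs["T", 1], 0.45)
  expect_equal(pw@probs["C", 1], 0.05)

  expect_identical(length(pwmFromConsensus("TTTWWW")), 6L)
  expect_error(pwmFromConsensus("AXC"), "IUPAC")
})

test_that("a length-1 PWM has the enumerable tail probability", {
  pwm <- randomPwm(1, seed = 1)
  pwm@scores[, 1] <- c(1, -1, -1, -1)
  pwm@background <- rep(0.25, 4)
  hit <- pwmScanPvalue(pwm, "A")
  expect_equal(hit$p_value, 0.25)
  expect_equal(hit$score, 1)
})

test_that("exact DP p-values match full enumeration for short PWMs", {
  for (seed in 1:8) {
    L <- sample(2:5, 1)
    pwm <- randomPwm(L, seed = seed)
    tailFun <- enumPwmTail(pwm, NULL)
    set.seed(seed + 100)
    seqv <- paste(sample(c("A", "C", "G", "T"), L + 6, replace = TRUE),
      collapse = "")
    hit <- pwmScanPvalue(pwm, seqv)
    delta <- L * 1e-4
    expect_gte(hit$p_value, tailFun(hit$score + delta) - 1e-12)
    expect_lte(hit$p_value, tailFun(hit$score - delta) + 1e-12)
  }
})

test_that("scanning the consensus itself gives the maximal score and minimal p", {
  pwm <- pwmFromConsensus("TATAAT")
  best <- pwmScanPvalue(pwm, "TATAAT")
  expect_equal(best$score, sum(apply(pwmScores(pwm), 2, max)))
  worse <- pwmScanPvalue(pwm, "TACAAT")
  expect_lt(worse$score, best$score)
  expect_gte(worse$p_value, best$p_value)
})

test_that("windows containing N are skipped and all-N input yields no hit", {
  pwm <- pwmFromConsensus("AAAA")
  hit <- pwmScanPvalue(pwm, "NNAAAANN")
  expect_identical(hit$offset, 3L)
  none <- pwmScanPvalue(pwm, "NNNNN")
  expect_true(is.na(none$p_value))
})

test_that("promoter classification finds planted promoters, strength is monotone", {
  cfg <- simConfig(seed = 9, nGenes = 40L, contigLength = 100000L)
  sim <- makeGenomeAnnotation(cfg)
  tg <- sim$truth$genes
  res <- classifyPromoters(sim$genes, sim$genome)
  planted <- res$promoter[match(tg$gene_id[tg$promoter], res$gene_id)]
  expect_true(all(planted))
  expect_true(all(res$strength_p[match(tg$gene_id[tg$promoter], res$gene_id)] <
    stats::median(res$strength_p[match(tg$gene_id[!tg$promoter], res$gene_id)])))

  ## genes without a TSS are excluded and reported
  noTss <- sim$genes
  noTss$tss[1] <- NA
  res2 <- classifyPromoters(noTss, sim$genome)
  expect_false(noTss$gene_id[1] %in% res2$gene_id)
  expect_true(noTss$gene_id[1] %in% attr(res2, "excluded"))
})

test_that("a mismatched promoter instance scores below the exact instance", {
  pwm <- promoterPwm()
  exact <- pwmScanPvalue(pwm, "GAAAAGGTTTATA")
  mm2 <- pwmScanPvalue(pwm, "GACAAGGTTTGTA")
  expect_lt(mm2$score, exact$score)
})

test_that("poly(U) calls follow the windowed T-count rule", {
  g <- tinyGenome(paste0(strrep("C", 50), "TTTTTTTT",
    strrep("A", 50), "TTTATTTA", strrep("C", 50)))
  ends <- data.frame(contig = "c1", strand = "+",
    position = c(60L, 118L, 40L))
  res <- classifyPolyU(ends, g)
  expect_identical(res$polyU, c(TRUE, TRUE, FALSE)) # 8T, 6-of-8 boundary, C-only
  expect_identical(res$max_u[3], 0L)
})

test_that("nucleotide enrichment matches its log-ratio definition and is null-centred", {
  g <- tinyGenome(len = 30000)
  genes <- geneModels("g1", "c1", 1000, 1500, "+")
  ig <- intergenicIntervals(genes, c(c1 = 30000L))
  ## group with T frequency 0.5 at position 1
  grp <- c(rep("TA", 50), rep("AA", 50))
  enr <- nucleotideEnrichment(grp, g, ig, nBackground = 200000L, seed = 2)
  bg <- attr(enr, "background")
  expect_equal(unname(enr["T", 1]),
    log2((0.5 + 1e-4) / (bg[["T"]] + 1e-4)), tolerance = 1e-9)

  ## windows sampled from the background itself are centred at zero
  set.seed(7)
  chars <- strsplit(as.character(g[["c1"]]), "")[[1]]
  starts <- sample(2000:29000, 1200)
  nullGrp <- vapply(starts, function(s)
    paste(chars[s:(s + 9)], collapse = ""), character(1))
  enr0 <- nucleotideEnrichment(nullGrp, g, ig, nBackground = 100000L,
    seed = 3)
  expect_lt(mean(abs(enr0)), 0.12)
  ## and smaller than for a quarter-sized group (decreasing with n)
  enrQ <- nucleotideEnrichment(nullGrp[1:300], g, ig,
    nBackground = 100000L, seed = 3)
  expect_lt(mean(abs(enr0)), mean(abs(enrQ)))
  expect_error(nucleotideEnrichment(grp, g, ig[0], seed = 1), "empty")
})

test_that("leadered/leaderless chi-square matches the hand-computed table", {
  ## [[10,90],[30,70]]: expected 20/80/20/80 -> X2 = 12.5
  res <- leaderedTest(list(up = c(rep(0, 10), rep(5, 90))),
    control = c(rep(0, 30), rep(9, 70)))
  expect_equal(res$statistic, 12.5)
  expect_equal(res$p, stats::pchisq(12.5, df = 1, lower.tail = FALSE))
  expect_equal(res$leaderless_prop, 0.1)

  same <- leaderedTest(list(g = c(rep(0, 3), rep(4, 9))),
    control = c(rep(0, 10), rep(4, 30)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)

  allLead <- leaderedTest(list(g = rep(9, 20)), control = rep(9, 50))
  expect_equal(allLead$leaderless_prop, 0)
  expect_equal(allLead$statistic, 0)

  expect_error(leaderedTest(list(g = numeric()), control = c(0, 1)), "empty")
})

test_that("regulon scanning recovers planted palindromic sites on both strands", {
  cfg <- simConfig(seed = 12, nGenes = 60L, contigLength = 150000L,
    regulonFraction = 0.2)
  sim <- makeGenomeAnnotation(cfg)
  tg <- sim$truth$genes
  hits <- regulonScan(sim$genes, sim$genome)
  planted <- tg$gene_id[tg$regulon]
  expect_true(all(planted %in% hits$gene_id))
  m <- merge(hits, tg[tg$regulon, c("gene_id", "regulon_offset")])
  expect_identical(m$offset, m$regulon_offset)

  ## palindrome: reverse-complement scan of a window agrees
  pwm <- regulonPwm()
  win <- senseWindow(sim$genome, tg$contig[1], tg$tss[1], tg$strand[1],
    -100L, -1L)
  fwd <- pwmScanPvalue(pwm, win)
  rcv <- pwmScanPvalue(pwm,
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(win))))
  expect_equal(fwd$score, rcv$score, tolerance = 1e-9)

  expect_identical(nrow(regulonScan(sim$genes, sim$genome, alpha = 0)), 0L)
})

test_that("CAI follows the Sharp-Li conventions", {
  ## gene built from the reference's preferred codons -> CAI = 1
  ref <- paste(rep(c("GCT", "AAA", "GAA", "CGT"), 10), collapse = "")
  gene1 <- paste(rep(c("GCT", "AAA"), 3), collapse = "")
  seq <- paste0(ref, gene1)
  g <- tinyGenome(seq)
  genes <- geneModels(c("ref", "g1"), "c1", c(1, nchar(ref) + 1),
    c(nchar(ref), nchar(seq)), c("+", "+"))
  res <- sequenceComposition(genes, g, "ref")
  expect_equal(res$cai[res$gene_id == "g1"], 1)

  ## CAI is invariant under synonymous-codon reordering and lies in (0, 1]
  gene2 <- paste(c("GCT", "AAA", "GCT", "AAA"), collapse = "")
  gene2b <- paste(c("AAA", "GCT", "AAA", "GCT"), collapse = "")
  seq2 <- paste0(ref, gene2, gene2b)
  g2 <- tinyGenome(seq2)
  genes2 <- geneModels(c("ref", "a", "b"), "c1",
    c(1, nchar(ref) + 1, nchar(ref) + 13),
    c(nchar(ref), nchar(ref) + 12, nchar(ref) + 24), "+")
  res2 <- sequenceComposition(genes2, g2, "ref")
  expect_equal(res2$cai[res2$gene_id == "a"], res2$cai[res2$gene_id == "b"])
  expect_true(all(res2$cai > 0 & res2$cai <= 1))

  ## geometric mean over per-codon relative adaptiveness
  w <- attr(res, "w")
  gene1Codons <- c("GCT", "AAA", "GCT", "AAA", "GCT", "AAA")
  expect_equal(res$cai[res$gene_id == "g1"],
    exp(mean(log(w[gene1Codons]))))

  ## length not divisible by 3 -> skipped with warning
  genes3 <- geneModels(c("ref", "bad"), "c1", c(1, nchar(ref) + 1),
    c(nchar(ref), nchar(ref) + 4), c("+", "+"))
  expect_warning(res3 <- sequenceComposition(genes3, g, "ref"), "multiple")
  expect_false("bad" %in% res3$gene_id)
})

test_that("a two-codon gene's CAI is the geometric mean of its w values", {
  ## reference: GCT 7.5x GCA (w_GCA = 0.125 after pseudocount tweak is
  ## avoided by exact counts), AAA 2x AAG
  ref <- paste(c(rep("GCA", 1), rep("GCT", 15), rep("AAG", 3), rep("AAA", 7)),
    collapse = "")
  gene <- paste0("AAG", "GCA") # w = {(3.5/7.5), (1.5/15.5)}
  seqv <- paste0(ref, gene)
  g <- tinyGenome(seqv)
  genes <- geneModels(c("ref", "g"), "c1", c(1, nchar(ref) + 1),
    c(nchar(ref), nchar(seqv)), "+")
  res <- sequenceComposition(genes, g, "ref")
  w1 <- 3.5 / 7.5
  w2 <- 1.5 / 15.5
  expect_equal(res$cai[res$gene_id == "g"], sqrt(w1 * w2))
})

test_that("GC content is the G+C fraction of the coding sequence", {
  seqv <- paste0(strrep("GCGC", 3), strrep("ATAT", 3))
  g <- tinyGenome(paste0(seqv, "AAA"))
  genes <- geneModels("g", "c1", 1, 24, "+")
  res <- sequenceComposition(genes, g, "g")
  expect_equal(res$gc, 0.5)
})
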