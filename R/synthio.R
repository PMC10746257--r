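## Synthetic thermal-stress study generator. Everything is deterministic
## under (seed, config); stage-specific seeds are derived from cfg@seed by
## small fixed offsets so stages can be re-simulated independently.

IUPAC_BASES <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

## consensus anchors of the archaeal core promoter and the palindromic
## heat-shock regulator site used by the generator and the classifiers
BRE_CONSENSUS <- "SWAAA"
TATA_CONSENSUS <- "TTTWWW"
PROMOTER_CONSENSUS <- "SWAAANNTTTWWW" # BRE + 2 nt spacer + TATA
REGULON_CONSENSUS <- "AAAGTTAACTTT" # palindromic (reverse complement = itself)
PROMOTER_OFFSET <- -38L # sense offset of the planted promoter instance

sampleConsensusInstance <- function(consensus) {
  paste(vapply(strsplit(consensus, "")[[1]], function(code) {
    opts <- IUPAC_BASES[[code]]
    if (is.null(opts)) stop("invalid IUPAC code: ", code)
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, character(1)), collapse = "")
}

## genomic indices and letters for planting a sense-strand sequence at
## transcript-orientation offsets [from, from+nchar-1] relative to anchor
## (returned instead of applied, so many plants can be written in one
## vectorized assignment)
plantSense <- function(anchor, strand, from, instance) {
  n <- nchar(instance)
  if (strand == "+") {
    lo <- anchor + from
    list(idx = lo:(lo + n - 1L), letters = strsplit(instance, "")[[1]])
  } else {
    hi <- anchor - from
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(instance)))
    list(idx = (hi - n + 1L):hi, letters = strsplit(rc, "")[[1]])
  }
}

applyPlants <- function(chars, plants) {
  if (!length(plants)) return(chars)
  chars[unlist(lapply(plants, `[[`, "idx"))] <-
    unlist(lapply(plants, `[[`, "letters"))
  chars
}

#' Condition-profile templates for planted clusters
#'
#' Deterministic, mutually distinct log2 fold-change profiles over the
#' non-control conditions; template `k` follows a cosine of frequency `k`
#' along the condition axis, scaled by `amplitude`, so any two templates
#' differ in shape (not just scale) and survive per-gene z-scoring.
#'
#' @param k number of templates.
#' @param conditions condition labels including `"Ctrl"`.
#' @param amplitude log2FC scale of the profiles.
#' @return a `k` x `length(conditions)` matrix (Ctrl column 0).
#' @export
clusterTemplates <- function(k, conditions, amplitude = 2) {
  stress <- setdiff(conditions, "Ctrl")
  m <- length(stress)
  tpl <- matrix(0, nrow = k, ncol = length(conditions),
    dimnames = list(paste0("T", seq_len(k)), conditions))
  for (i in seq_len(k)) {
    phase <- pi * (i - 1) / max(1, k - 1)
    tpl[i, stress] <- amplitude * cos(pi * i * (seq_len(m) - 1) / (m - 1) + phase)
  }
  tpl
}

#' Generate a synthetic genome, annotation and ground truth
#'
#' Places non-overlapping genes on both strands with at least 400 nt of
#' intergenic space, assigns 5' UTRs (a configurable fraction leaderless),
#' plants concrete BRE/TATA promoter instances at -38..-26 relative to the
#' TSS, palindromic regulator sites upstream of selected genes, primary
#' (plus optional secondary and internal) 3' ends with heights, U-rich
#' terminator stretches at planted primary ends, functional category labels
#' with one overrepresented category among profile-cluster genes, and
#' per-condition planted log2 fold changes for RNA and protein.
#'
#' @param cfg a [SimConfig-class].
#' @return a list with elements `genome` (named
#'   [Biostrings::DNAStringSet]), `genes` (gene `GRanges`) and `truth`
#'   (list: per-gene data.frame `genes`, matrices `rna_l2fc` and
#'   `protein_l2fc` over all conditions, and `templates`).
#' @examples
#' sim <- makeGenomeAnnotation(simConfig(seed = 1, nGenes = 20,
#'   contigLength = 60000L))
#' @export
makeGenomeAnnotation <- function(cfg) {
  stopifnot(is(cfg, "SimConfig"))
  set.seed(cfg@seed)
  L <- cfg@contigLength
  n <- cfg@nGenes
  probs <- c((1 - cfg@gc) / 2, cfg@gc / 2, cfg@gc / 2, (1 - cfg@gc) / 2)
  chars <- sample(BASES, L, replace = TRUE, prob = probs)

  ## --- gene placement: margin + alternating gaps, >= 400 nt intergenic ---
  lens <- 3L * sample(100:600, n, replace = TRUE)
  ## minimum gap of 550 keeps every planted upstream feature (promoter,
  ## regulator site) clear of the neighbouring gene's 3'-end features
  gaps <- 550L + sample(0:200, n, replace = TRUE)
  ## 300-nt leading margin: room for the longest 5' UTR (150) plus the
  ## deepest planted upstream element (regulator site down to -96)
  starts <- 300L + cumsum(c(0L, lens[-n] + gaps[-n]))
  ends <- starts + lens - 1L
  if (ends[n] + 400L > L)
    stop(sprintf("genome too small: need >= %d nt to place %d genes",
      ends[n] + 400L, n))
  strandv <- sample(c("+", "-"), n, replace = TRUE)
  ids <- sprintf("g%04d", seq_len(n))

  ## --- 5' UTRs, TSS ---
  leaderless <- stats::runif(n) < cfg@leaderlessFraction
  utr5 <- ifelse(leaderless, 0L, 1L + stats::rgeom(n, 1 / 30))
  utr5 <- pmin(utr5, 150L)
  tss <- ifelse(strandv == "+", starts - utr5, ends + utr5)

  ## --- planted promoters (BRE + spacer + TATA at -38..-26 rel TSS) ---
  promoter <- stats::runif(n) < cfg@promoterFraction
  plants <- lapply(which(promoter), function(i)
    plantSense(tss[i], strandv[i], PROMOTER_OFFSET,
      sampleConsensusInstance(PROMOTER_CONSENSUS)))

  ## --- planted palindromic regulator sites upstream of the TSS ---
  regulon <- stats::runif(n) < cfg@regulonFraction
  regOffset <- rep(NA_integer_, n)
  for (i in which(regulon)) {
    regOffset[i] <- -sample(45:85, 1L) - nchar(REGULON_CONSENSUS) + 1L
    plants <- c(plants, list(plantSense(tss[i], strandv[i], regOffset[i],
      REGULON_CONSENSUS)))
  }

  ## --- 3' ends: primary / secondary / internal, with heights ---
  ## >= 1 nt so the planted primary end lies strictly downstream of the
  ## gene body (an end on the boundary is internal by the classification
  ## rule)
  utr3 <- 1L + pmin(stats::rgeom(n, 1 / 40), 249L)
  bnd3 <- ifelse(strandv == "+", ends, starts)
  dirv <- ifelse(strandv == "+", 1L, -1L)
  primaryPos <- bnd3 + dirv * utr3
  hPrim <- pmax(cfg@endHeightMin,
    stats::rlnorm(n, cfg@endHeightMeanLog, cfg@endHeightSdLog))

  hasSec <- stats::runif(n) < cfg@secondaryFraction
  secDelta <- integer(n)
  secDelta[hasSec] <- sample(30:140, sum(hasSec), replace = TRUE)
  ok <- hasSec & (utr3 + secDelta) <= 295L
  hasSec <- ok
  secondaryPos <- ifelse(hasSec, bnd3 + dirv * (utr3 + secDelta), NA_integer_)
  hSec <- ifelse(hasSec, pmax(cfg@endHeightMin, 0.4 * hPrim), NA_real_)

  hasInt <- stats::runif(n) < cfg@internalFraction & lens > 60L
  intOff <- integer(n)
  intOff[hasInt] <- vapply(which(hasInt),
    function(i) sample(20:(lens[i] - 20L), 1L), integer(1))
  internalPos <- ifelse(hasInt, starts + intOff, NA_integer_)
  hInt <- ifelse(hasInt, pmax(cfg@endHeightMin, 0.2 * hPrim), NA_real_)

  ## --- planted poly(U) terminators: 16 nt, >= 13 T, at -13..+2 rel end ---
  polyU <- stats::runif(n) < cfg@polyUFraction
  for (i in which(polyU)) {
    u <- rep("T", 16L)
    swap <- sample(16L, 3L)
    u[swap] <- sample(BASES, 3L, replace = TRUE)
    plants <- c(plants, list(plantSense(as.integer(primaryPos[i]), strandv[i],
      -13L, paste(u, collapse = ""))))
  }
  chars <- applyPlants(chars, plants)

  ## --- profile clusters and planted fold changes ---
  conds <- cfg@conditions
  cluster <- integer(n)
  if (cfg@kTrue > 0L) {
    member <- stats::runif(n) < cfg@clusterFraction
    cluster[member] <- sample(cfg@kTrue, sum(member), replace = TRUE)
  }
  tpl <- clusterTemplates(max(cfg@kTrue, 1L), conds, cfg@clusterAmplitude)
  rna <- matrix(0, n, length(conds), dimnames = list(ids, conds))
  for (j in which(conds != "Ctrl")) {
    free <- cluster == 0L
    de <- free & stats::runif(n) >= cfg@pi0
    if (cfg@lengthBiasStrength > 0) {
      pr <- stats::plogis(cfg@lengthBiasStrength *
        scale(lens)[, 1] + stats::qlogis(1 - cfg@pi0))
      de <- free & stats::runif(n) < pr
    }
    rna[de, j] <- stats::rnorm(sum(de), cfg@deMu, cfg@deSigma)
    inCl <- cluster > 0L
    rna[inCl, j] <- tpl[cluster[inCl], j] +
      stats::rnorm(sum(inCl), 0, cfg@clusterSigma)
  }
  stressCols <- conds != "Ctrl"
  ## protein effects mix the RNA effect with independent noise of matched
  ## marginal sd, giving correlation rho; an all-null RNA layer (sd 0)
  ## yields an all-null protein layer
  s <- stats::sd(rna[, stressCols])
  if (!is.finite(s)) s <- 0
  rho <- cfg@rnaProteinRho
  prot <- matrix(0, n, length(conds), dimnames = dimnames(rna))
  prot[, stressCols] <- rho * rna[, stressCols] +
    sqrt(1 - rho^2) * matrix(stats::rnorm(n * sum(stressCols), 0, s),
      nrow = n)

  ## --- functional categories, one enriched among cluster (DE) genes ---
  cats <- sprintf("C%02d", seq_len(cfg@nCategories))
  baseP <- rep(1 / cfg@nCategories, cfg@nCategories)
  arcog <- sample(cats, n, replace = TRUE, prob = baseP)
  if (cfg@enrichedCategory >= 1L) {
    pe <- baseP
    pe[cfg@enrichedCategory] <- cfg@enrichmentFold / cfg@nCategories
    pe <- pe / sum(pe)
    sel <- cluster > 0L
    arcog[sel] <- sample(cats, sum(sel), replace = TRUE, prob = pe)
  }

  genomeSeq <- Biostrings::DNAStringSet(paste(chars, collapse = ""))
  names(genomeSeq) <- "chr"
  genes <- geneModels(ids, "chr", starts, ends, strandv,
    tss = tss, utr5_len = utr5, arcog = arcog,
    contigLengths = c(chr = L))
  truthGenes <- data.frame(
    gene_id = ids, contig = "chr", start = starts, end = ends,
    strand = strandv, length = lens, tss = tss, utr5_len = utr5,
    promoter = promoter, regulon = regulon, regulon_offset = regOffset,
    primary_pos = as.integer(primaryPos), primary_height = hPrim,
    utr3_len = utr3,
    secondary_pos = as.integer(secondaryPos), secondary_height = hSec,
    internal_pos = as.integer(internalPos), internal_height = hInt,
    polyU = polyU, cluster = cluster, arcog = arcog,
    stringsAsFactors = FALSE
  )
  list(
    genome = genomeSeq, genes = genes,
    truth = list(genes = truthGenes, rna_l2fc = rna, protein_l2fc = prot,
      templates = tpl[seq_len(max(cfg@kTrue, 1L)), , drop = FALSE])
  )
}

#' Simulate Term-seq 3'-end count tracks
#'
#' For each replicate, each planted 3' end receives a negative-binomial
#' number of reads (mean = planted height x replicate size factor), each
#' read jittered by an integer-rounded Gaussian offset; uniform background
#' single-read positions are added at `backgroundRate` per nt per strand.
#' Replicate size factors are drawn log-uniformly in [0.5, 2].
#'
#' @param cfg a [SimConfig-class].
#' @param truth truth list from [makeGenomeAnnotation()].
#' @return a list of `nReplicates` elements, each a list with raw
#'   [EndTrack-class]s `plus` and `minus` sharing the replicate's library
#'   total.
#' @export
simulateTermseq <- function(cfg, truth) {
  set.seed(cfg@seed + 1L)
  tg <- truth$genes
  L <- cfg@contigLength
  endsTab <- rbind(
    data.frame(pos = tg$primary_pos, strand = tg$strand, h = tg$primary_height),
    data.frame(pos = tg$secondary_pos, strand = tg$strand, h = tg$secondary_height),
    data.frame(pos = tg$internal_pos, strand = tg$strand, h = tg$internal_height)
  )
  endsTab <- endsTab[!is.na(endsTab$pos), ]
  lapply(seq_len(cfg@nReplicates), function(r) {
    sf <- exp(stats::runif(1, log(0.5), log(2)))
    acc <- list("+" = integer(0), "-" = integer(0))
    for (i in seq_len(nrow(endsTab))) {
      nReads <- stats::rnbinom(1, mu = endsTab$h[i] * sf, size = 1 / cfg@dispersion)
      if (nReads == 0) next
      offs <- if (cfg@jitterSd > 0)
        as.integer(round(stats::rnorm(nReads, 0, cfg@jitterSd))) else integer(nReads)
      p <- endsTab$pos[i] + offs
      p <- p[p >= 1L & p <= L]
      acc[[endsTab$strand[i]]] <- c(acc[[endsTab$strand[i]]], p)
    }
    for (s in c("+", "-")) {
      nbg <- stats::rpois(1, cfg@backgroundRate * L)
      if (nbg > 0) acc[[s]] <- c(acc[[s]], sample.int(L, nbg, replace = TRUE))
    }
    tabs <- lapply(acc, function(p) table(p))
    total <- sum(vapply(acc, length, integer(1)))
    mk <- function(s) endTrack("chr", s,
      pos = as.integer(names(tabs[[s]])), count = as.numeric(tabs[[s]]),
      contigLength = L, libraryTotal = total)
    list(plus = mk("+"), minus = mk("-"))
  })
}

#' Simulate RNA counts and protein intensities
#'
#' RNA counts are negative binomial around
#' `baseline x 2^log2FC x size factor`; protein intensities are lognormal
#' around a baseline tied to the RNA baseline with the planted protein
#' effects, a per-sample scale distortion, and values falling below the
#' 5th percentile of the intensity distribution censored to `NA`
#' (emulating undetected proteins).
#'
#' @param cfg a [SimConfig-class].
#' @param truth truth list from [makeGenomeAnnotation()].
#' @return list with [OmicsExperiment-class] elements `rna` and `protein`.
#' @export
simulateOmics <- function(cfg, truth) {
  set.seed(cfg@seed + 2L)
  tg <- truth$genes
  n <- nrow(tg)
  conds <- cfg@conditions
  design <- expand.grid(replicate = seq_len(cfg@nReplicates),
    condition = conds, stringsAsFactors = FALSE)[, 2:1]
  ns <- nrow(design)
  baseline <- stats::rlnorm(n, cfg@baselineMeanLog, cfg@baselineSdLog)
  sfRna <- exp(stats::runif(ns, log(0.5), log(2)))
  mu <- baseline * 2^truth$rna_l2fc[, design$condition, drop = FALSE]
  counts <- matrix(stats::rnbinom(n * ns, mu = sweep(mu, 2, sfRna, "*"),
    size = 1 / cfg@dispersion), n, ns)
  dimnames(counts) <- list(tg$gene_id, paste(design$condition, design$replicate,
    sep = "_"))
  rna <- omicsExperiment(counts, design$condition, design$replicate,
    kind = "rna", lengths = tg$length)

  protBase <- 2^(0.8 * log2(baseline) + 10)
  scaleP <- 2^stats::rnorm(ns, 0, 0.3)
  lmu <- log2(protBase) + truth$protein_l2fc[, design$condition, drop = FALSE]
  intens <- 2^(lmu + matrix(stats::rnorm(n * ns, 0, cfg@proteinSigma), n, ns))
  intens <- sweep(intens, 2, scaleP, "*")
  lod <- stats::quantile(intens, 0.05)
  intens[intens < lod] <- NA
  dimnames(intens) <- dimnames(counts)
  protein <- omicsExperiment(intens, design$condition, design$replicate,
    kind = "protein")
  list(rna = rna, protein = protein)
}

#' Simulate full-length (long-read) transcript intervals
#'
#' Each gene receives `nReads` reads spanning its TSS to its primary 3'
#' end, with integer Gaussian jitter of sd `endJitter` on both boundaries.
#' For pairs listed in `operonPairs`, each read of the upstream gene
#' extends through the downstream gene with the pair's readthrough
#' probability.
#'
#' @param cfg a [SimConfig-class].
#' @param truth truth list from [makeGenomeAnnotation()].
#' @param operonPairs optional data.frame with columns `up`, `down`
#'   (gene ids) and `readthrough` (probability).
#' @param nReads reads per gene.
#' @param endJitter boundary jitter sd in nt (0 = exact).
#' @return data.frame of read intervals (`contig`, `start`, `end`,
#'   `strand`).
#' @export
simulateLongreads <- function(cfg, truth, operonPairs = NULL, nReads = 20L,
                              endJitter = 5) {
  set.seed(cfg@seed + 3L)
  tg <- truth$genes
  rt <- stats::setNames(rep(0, nrow(tg)), tg$gene_id)
  down <- stats::setNames(rep(NA_character_, nrow(tg)), tg$gene_id)
  if (!is.null(operonPairs)) {
    rt[operonPairs$up] <- operonPairs$readthrough
    down[operonPairs$up] <- operonPairs$down
  }
  out <- lapply(seq_len(nrow(tg)), function(i) {
    from5 <- tg$tss[i]
    to3 <- tg$primary_pos[i]
    thru <- stats::runif(nReads) < rt[tg$gene_id[i]]
    if (!is.na(down[tg$gene_id[i]])) {
      j <- match(down[tg$gene_id[i]], tg$gene_id)
      to3 <- ifelse(thru, tg$primary_pos[j], to3)
    }
    j5 <- if (endJitter > 0) round(stats::rnorm(nReads, 0, endJitter))
      else rep(0, nReads)
    j3 <- if (endJitter > 0) round(stats::rnorm(nReads, 0, endJitter))
      else rep(0, nReads)
    a <- from5 + if (tg$strand[i] == "+") -abs(j5) else abs(j5)
    b <- to3 + if (tg$strand[i] == "+") j3 else -j3
    data.frame(
      contig = tg$contig[i],
      start = pmax(1L, pmin(a, b)),
      end = pmin(cfg@contigLength, pmax(a, b)),
      strand = tg$strand[i]
    )
  })
  do.call(rbind, out)
}

#' Write a full simulated study to disk
#'
#' Emits FASTA, GFF3 (with `tss`/`utr5_len`/`arcog` attributes), per-strand
#' per-replicate bedGraph end tracks, RNA/protein TSV matrices, a design
#' TSV and a per-gene truth TSV.
#'
#' @param sim list from [makeGenomeAnnotation()].
#' @param tracks list from [simulateTermseq()].
#' @param omics list from [simulateOmics()].
#' @param dir output directory (created if needed).
#' @return named character vector of the files written, invisibly.
#' @export
writeSimulation <- function(sim, tracks, omics, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- c(genome = file.path(dir, "genome.fa"),
    genes = file.path(dir, "genes.gff3"),
    truth = file.path(dir, "truth.tsv"),
    rna = file.path(dir, "rna_counts.tsv"),
    protein = file.path(dir, "protein_intensity.tsv"),
    design = file.path(dir, "design.tsv"))
  writeGenomeFasta(sim$genome, f[["genome"]])
  writeGff3Genes(sim$genes, f[["genes"]])
  utils::write.table(sim$truth$genes, f[["truth"]], sep = "\t",
    quote = FALSE, row.names = FALSE)
  wr <- function(se, path) {
    m <- SummarizedExperiment::assay(se)
    utils::write.table(data.frame(gene = rownames(m), m, check.names = FALSE),
      path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wr(omics$rna, f[["rna"]])
  wr(omics$protein, f[["protein"]])
  utils::write.table(
    as.data.frame(SummarizedExperiment::colData(omics$rna)),
    f[["design"]], sep = "\t", quote = FALSE, row.names = TRUE)
  for (r in seq_along(tracks)) {
    for (s in c("plus", "minus")) {
      p <- file.path(dir, sprintf("termseq_rep%d_%s.bedgraph", r, s))
      writeEndTrack(tracks[[r]][[s]], p)
      f[[sprintf("termseq_rep%d_%s", r, s)]] <- p
    }
  }
  invisible(f)
}
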