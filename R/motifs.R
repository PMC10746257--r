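## Promoter/terminator sequence features: consensus-seeded PWMs with exact
## score-distribution p-values, BRE/TATA promoter classification and
## strength, poly(U) terminator calls, nucleotide enrichment against
## intergenic background, leadered/leaderless testing, palindromic regulon
## scanning, and codon adaptation / GC composition.

#' Build a PWM from a degenerate IUPAC consensus
#'
#' At each consensus position a probability mass of `matchProb` is split
#' uniformly over the allowed bases and the remainder uniformly over the
#' disallowed bases (positions allowing all four bases get the background
#' uniform 1/4). Scores are log2 odds against `background`.
#'
#' @param consensus IUPAC string (e.g. `"SWAAA"` for the BRE element).
#' @param matchProb probability mass on the allowed bases, in (0.5, 1).
#' @param background base probabilities (A, C, G, T).
#' @param pseudocount probability added to numerator and denominator before
#'   taking log odds (default 0).
#' @return a [MotifPWM-class].
#' @examples
#' pwmFromConsensus("TTTWWW")
#' @export
pwmFromConsensus <- function(consensus, matchProb = 0.9,
                             background = rep(0.25, 4), pseudocount = 0) {
  stopifnot(matchProb > 0.5, matchProb < 1)
  codes <- strsplit(toupper(consensus), "")[[1]]
  probs <- vapply(codes, function(code) {
    opts <- IUPAC_BASES[[code]]
    if (is.null(opts)) stop("invalid IUPAC code: ", code)
    p <- numeric(4)
    names(p) <- BASES
    if (length(opts) == 4L) {
      p[] <- 0.25
    } else {
      p[opts] <- matchProb / length(opts)
      p[setdiff(BASES, opts)] <- (1 - matchProb) / (4 - length(opts))
    }
    p
  }, numeric(4))
  rownames(probs) <- BASES
  background <- background / sum(background)
  scores <- log2((probs + pseudocount) / (background + pseudocount))
  new("MotifPWM", probs = probs, scores = scores,
    background = background, pseudocount = pseudocount)
}

#' The package's archaeal promoter (BRE + TATA) PWM
#' @param matchProb see [pwmFromConsensus()].
#' @return a [MotifPWM-class] for BRE (`SWAAA`), a 2-nt spacer and TATA
#'   (`TTTWWW`).
#' @export
promoterPwm <- function(matchProb = 0.9) {
  pwmFromConsensus(PROMOTER_CONSENSUS, matchProb = matchProb)
}

#' The package's palindromic heat-shock regulator PWM
#' @param matchProb see [pwmFromConsensus()].
#' @return a [MotifPWM-class] for the palindromic site `AAAGTTAACTTT`.
#' @export
regulonPwm <- function(matchProb = 0.9) {
  pwmFromConsensus(REGULON_CONSENSUS, matchProb = matchProb)
}

## exact null distribution of the window score under the background model,
## on an integer grid of step eps (dynamic-programming convolution)
pwmScoreDistribution <- function(pwm, eps = 1e-4) {
  k <- round(pwm@scores / eps)
  L <- ncol(k)
  lo <- sum(apply(k, 2, min))
  hi <- sum(apply(k, 2, max))
  dist <- 1
  offset <- 0L # dist[i] = P(sum = offset + i - 1)
  for (j in seq_len(L)) {
    kj <- k[, j]
    newLo <- offset + min(kj)
    newHi <- offset + length(dist) - 1L + max(kj)
    nd <- numeric(newHi - newLo + 1L)
    for (b in 1:4) {
      sh <- offset + kj[b] - newLo
      idx <- seq_along(dist) + sh
      nd[idx] <- nd[idx] + dist * pwm@background[b]
    }
    dist <- nd
    offset <- newLo
  }
  upper <- rev(cumsum(rev(dist)))
  list(kmat = k, eps = eps, offset = offset, upper = upper, lo = lo, hi = hi)
}

## P(window score >= observed grid score) under the background model
pwmTailP <- function(sd, kObs) {
  i <- kObs - sd$offset + 1L
  if (i <= 1L) return(1)
  if (i > length(sd$upper)) return(0)
  sd$upper[i]
}

#' Scan a sequence with a PWM and report the best hit with exact p-value
#'
#' Slides the PWM over every window of the (sense-strand) sequence, skips
#' windows containing `N`, and reports the best-scoring window together
#' with the exact probability that a random background sequence of the
#' motif length scores at least as high. The p-value is exact on a score
#' grid of step `eps` (scores are discretized by rounding; the same grid is
#' used for the observed score and the null distribution).
#'
#' @param pwm a [MotifPWM-class].
#' @param sequence nucleotide string, length >= motif length.
#' @param eps score discretization step (default 1e-4).
#' @param scoreDist optional precomputed result of the internal null-score
#'   distribution (reuse across many scans of the same PWM).
#' @return a one-row data.frame `offset` (1-based start of the best
#'   window), `score` (log2 odds), `p_value`; or a row of `NA`s when every
#'   window contains `N`.
#' @examples
#' pwm <- pwmFromConsensus("TTTWWW")
#' pwmScanPvalue(pwm, "GCGTTTATAGCG")
#' @export
pwmScanPvalue <- function(pwm, sequence, eps = 1e-4, scoreDist = NULL) {
  L <- length(pwm)
  chars <- strsplit(toupper(sequence), "")[[1]]
  if (length(chars) < L) stop("sequence shorter than the motif")
  if (is.null(scoreDist)) scoreDist <- pwmScoreDistribution(pwm, eps)
  code <- match(chars, BASES) # NA for N
  nWin <- length(chars) - L + 1L
  kScores <- rep(NA_integer_, nWin)
  for (s in seq_len(nWin)) {
    idx <- code[s:(s + L - 1L)]
    if (anyNA(idx)) next
    kScores[s] <- sum(scoreDist$kmat[cbind(idx, seq_len(L))])
  }
  if (all(is.na(kScores))) {
    return(data.frame(offset = NA_integer_, score = NA_real_,
      p_value = NA_real_))
  }
  best <- which.max(kScores)
  idx <- code[best:(best + L - 1L)]
  data.frame(
    offset = best,
    score = sum(pwm@scores[cbind(idx, seq_len(L))]),
    p_value = pwmTailP(scoreDist, kScores[best])
  )
}

#' Classify promoters and estimate promoter strength
#'
#' Scans the -50..+10 window around each TSS with the BRE/TATA PWM; a gene
#' is `+promoter` when the best hit's exact p-value is at most `alpha`.
#' Promoter strength is the best-hit p-value within -42..-19 (smaller =
#' stronger).
#'
#' @param genes gene `GRanges` with a `tss` column.
#' @param genome named [Biostrings::DNAStringSet].
#' @param pwm promoter PWM (default [promoterPwm()]).
#' @param window,strengthWindow signed offset ranges relative to the TSS.
#' @param alpha classification threshold on the exact p-value.
#' @return data.frame `gene_id`, `promoter` (logical), `promoter_p`,
#'   `strength_p`. Genes without a TSS (or too close to a contig edge,
#'   with a warning) are excluded; their ids are in attribute
#'   `"excluded"`.
#' @export
classifyPromoters <- function(genes, genome, pwm = promoterPwm(),
                              window = c(-50L, 10L),
                              strengthWindow = c(-42L, -19L), alpha = 1e-3) {
  sd0 <- pwmScoreDistribution(pwm)
  hasTss <- !is.na(genes$tss)
  excluded <- genes$gene_id[!hasTss]
  rows <- list()
  for (i in which(hasTss)) {
    ct <- as.character(GenomicRanges::seqnames(genes))[i]
    st <- as.character(GenomicRanges::strand(genes))[i]
    s1 <- senseWindow(genome, ct, genes$tss[i], st, window[1], window[2])
    s2 <- senseWindow(genome, ct, genes$tss[i], st, strengthWindow[1],
      strengthWindow[2])
    if (is.na(s1) || is.na(s2)) {
      warning("TSS of ", genes$gene_id[i], " too close to contig edge; skipped")
      excluded <- c(excluded, genes$gene_id[i])
      next
    }
    h1 <- pwmScanPvalue(pwm, s1, scoreDist = sd0)
    h2 <- pwmScanPvalue(pwm, s2, scoreDist = sd0)
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = genes$gene_id[i],
      promoter = !is.na(h1$p_value) && h1$p_value <= alpha,
      promoter_p = h1$p_value, strength_p = h2$p_value
    )
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(), promoter = logical(),
      promoter_p = numeric(), strength_p = numeric())
  }
  attr(out, "excluded") <- excluded
  out
}

#' Classify poly(U) terminator signals at primary 3' ends
#'
#' Extracts the sense-strand -35..+2 window around each primary 3' end; an
#' end is `+polyU` when some `uWindow`-nt subwindow contains at least
#' `minU` T (= U on the transcript).
#'
#' @param ends data.frame with `contig`, `strand`, `position` (primary end
#'   calls; extra columns are carried through).
#' @param genome named [Biostrings::DNAStringSet].
#' @param window signed offsets relative to the end (default -35..+2).
#' @param uWindow,minU subwindow length and minimum T count (defaults 8
#'   and 6).
#' @return `ends` with added `polyU` (logical) and `max_u` (maximum T
#'   count over subwindows). Ends whose window leaves the contig are
#'   dropped with a warning.
#' @export
classifyPolyU <- function(ends, genome, window = c(-35L, 2L), uWindow = 8L,
                          minU = 6L) {
  keep <- logical(nrow(ends))
  maxU <- integer(nrow(ends))
  for (i in seq_len(nrow(ends))) {
    s <- senseWindow(genome, ends$contig[i], ends$position[i],
      ends$strand[i], window[1], window[2])
    if (is.na(s)) {
      warning("window around end at ", ends$position[i],
        " leaves the contig; end skipped")
      next
    }
    keep[i] <- TRUE
    isT <- as.integer(strsplit(s, "")[[1]] == "T")
    cs <- cumsum(c(0L, isT))
    maxU[i] <- max(cs[(uWindow + 1L):length(cs)] -
      cs[1:(length(cs) - uWindow)])
  }
  out <- ends[keep, , drop = FALSE]
  out$max_u <- maxU[keep]
  out$polyU <- out$max_u >= minU
  out
}

#' Position-specific nucleotide enrichment against intergenic background
#'
#' Per-position base frequencies of a group of equal-length windows are
#' compared (log2 ratio) to the base distribution of `nBackground`
#' positions sampled uniformly with replacement from intergenic intervals.
#'
#' @param groupSeqs character vector of equal-length sense-strand windows.
#' @param genome named [Biostrings::DNAStringSet].
#' @param intergenic `GRanges` of intergenic intervals (see
#'   [intergenicIntervals()]).
#' @param nBackground background sample size (default 100000).
#' @param seed RNG seed for the background sampling.
#' @param pseudocount added to both frequencies before the ratio.
#' @return 4 x L matrix (rows A, C, G, T) of log2 enrichments; the
#'   background frequencies are in attribute `"background"`.
#' @export
nucleotideEnrichment <- function(groupSeqs, genome, intergenic,
                                 nBackground = 100000L, seed = 1L,
                                 pseudocount = 1e-4) {
  if (!length(groupSeqs)) stop("empty group")
  L <- unique(nchar(groupSeqs))
  if (length(L) != 1L) stop("group windows must have equal length")
  if (length(intergenic) == 0L) stop("empty intergenic set")
  mat <- do.call(rbind, strsplit(groupSeqs, ""))
  fg <- vapply(seq_len(L), function(j) {
    tab <- table(factor(mat[, j], levels = BASES))
    as.numeric(tab) / max(1L, sum(tab))
  }, numeric(4))
  rownames(fg) <- BASES

  chars <- unlist(lapply(GenomeInfoDb::seqlevels(intergenic), function(ct) {
    rr <- IRanges::ranges(intergenic[GenomicRanges::seqnames(intergenic) == ct])
    if (!length(rr)) return(character())
    strsplit(as.character(unlist(Biostrings::extractAt(genome[[ct]], rr))),
      "")[[1]]
  }))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  draw <- chars[sample.int(length(chars), nBackground, replace = TRUE)]
  bgTab <- table(factor(draw, levels = BASES))
  bg <- as.numeric(bgTab) / sum(bgTab)
  enr <- log2((fg + pseudocount) / (bg + pseudocount))
  attr(enr, "background") <- stats::setNames(bg, BASES)
  enr
}

#' Leaderless-vs-leadered chi-square test per regulation group
#'
#' For each group, forms the 2x2 table of leaderless (5' UTR = 0) versus
#' leadered (5' UTR >= 1) transcripts in the group against the control
#' set, and applies Pearson's chi-square test without continuity
#' correction (df = 1).
#'
#' @param groups named list of 5'-UTR length vectors, one per regulation
#'   group.
#' @param control 5'-UTR lengths of the control set.
#' @return data.frame `group`, `n`, `leaderless_prop`, `statistic`, `p`,
#'   `low_count` (TRUE when some expected cell is below 1; the statistic
#'   is still reported).
#' @examples
#' leaderedTest(list(up = c(rep(0, 10), rep(5, 90))),
#'   control = c(rep(0, 30), rep(5, 70)))
#' @export
leaderedTest <- function(groups, control) {
  stopifnot(length(control) > 0)
  rows <- lapply(names(groups), function(g) {
    u <- groups[[g]]
    if (!length(u)) stop("group '", g, "' is empty")
    tab <- rbind(
      group = c(leaderless = sum(u == 0), leadered = sum(u >= 1)),
      control = c(sum(control == 0), sum(control >= 1))
    )
    expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(tab %*% c(1, 1) == 0) || any(colSums(tab) == 0)) {
      stat <- 0; p <- 1
    } else {
      ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      stat <- unname(ht$statistic); p <- ht$p.value
    }
    data.frame(group = g, n = length(u),
      leaderless_prop = mean(u == 0),
      statistic = stat, p = p, low_count = any(expd < 1))
  })
  do.call(rbind, rows)
}

#' Scan upstream windows for a palindromic regulator motif
#'
#' Scans the sense strand and the reverse complement of the search window
#' upstream of each gene's TSS (or start codon when no TSS is known) and
#' reports the best hit per gene; for a palindromic PWM both strands agree
#' up to the score grid. Hits with p-value at most `alpha` are returned
#' ranked by score.
#'
#' @param genes gene `GRanges`.
#' @param genome named [Biostrings::DNAStringSet].
#' @param pwm palindromic [MotifPWM-class] (default [regulonPwm()]); a
#'   non-palindromic PWM triggers a warning but both strands are still
#'   scanned.
#' @param search signed offsets of the search window (default -100..-1).
#' @param alpha p-value threshold for reporting.
#' @return data.frame `gene_id`, `offset` (sense offset of the hit's
#'   5'-most base relative to the anchor), `strand_hit` (`"sense"` or
#'   `"antisense"`), `score`, `p_value`, ranked by decreasing score.
#' @export
regulonScan <- function(genes, genome, pwm = regulonPwm(),
                        search = c(-100L, -1L), alpha = 1e-4) {
  sc <- pwm@scores
  L <- ncol(sc)
  rcScores <- sc[4:1, L:1, drop = FALSE]
  dimnames(rcScores) <- dimnames(sc)
  if (max(abs(sc - rcScores)) > 1e-9)
    warning("PWM is not palindrome-symmetric; scanning both strands anyway")
  sd0 <- pwmScoreDistribution(pwm)
  rows <- list()
  for (i in seq_along(genes)) {
    ct <- as.character(GenomicRanges::seqnames(genes))[i]
    st <- as.character(GenomicRanges::strand(genes))[i]
    anchor <- if (!is.na(genes$tss[i])) genes$tss[i] else gene5pBoundary(genes)[i]
    s <- senseWindow(genome, ct, anchor, st, search[1], search[2])
    if (is.na(s)) next
    fwd <- pwmScanPvalue(pwm, s, scoreDist = sd0)
    rcSeq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    rev <- pwmScanPvalue(pwm, rcSeq, scoreDist = sd0)
    wlen <- nchar(s)
    if (!is.na(rev$score) && (is.na(fwd$score) || rev$score > fwd$score)) {
      best <- rev
      off <- search[1] + (wlen - (rev$offset + L - 1L))
      strandHit <- "antisense"
    } else {
      best <- fwd
      off <- search[1] + fwd$offset - 1L
      strandHit <- "sense"
    }
    if (is.na(best$p_value) || best$p_value > alpha) next
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = genes$gene_id[i], offset = off, strand_hit = strandHit,
      score = best$score, p_value = best$p_value
    )
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(gene_id = character(), offset = integer(),
      strand_hit = character(), score = numeric(), p_value = numeric()))
  }
  out[order(-out$score), , drop = FALSE]
}

## codons of each amino acid under the standard genetic code, excluding
## stops and singleton families (Met, Trp) for the CAI
caiCodonFamilies <- function() {
  gc <- Biostrings::GENETIC_CODE
  fam <- split(names(gc), gc)
  fam <- fam[!names(fam) %in% "*"]
  fam[vapply(fam, length, integer(1)) > 1L]
}

#' Codon adaptation index and GC content
#'
#' Relative adaptiveness `w(c) = f(c) / max f(synonymous)` is computed from
#' the pooled codon counts of `referenceSet` (pseudocount 0.5); the CAI of
#' a gene is the geometric mean of `w` over its codons, excluding stop
#' codons and amino acids encoded by a single codon (Met, Trp). GC is the
#' G+C fraction of the coding sequence.
#'
#' @param genes gene `GRanges`.
#' @param genome named [Biostrings::DNAStringSet].
#' @param referenceSet gene ids of the reference set (typically the most
#'   abundant 5% of proteins under control conditions).
#' @return data.frame `gene_id`, `cai`, `gc`; genes whose length is not a
#'   multiple of 3 are skipped with a warning. The `w` table is in
#'   attribute `"w"`.
#' @export
sequenceComposition <- function(genes, genome, referenceSet) {
  if (!length(referenceSet)) stop("reference set is empty")
  cds <- vapply(seq_along(genes), function(i) {
    senseWindow(genome, as.character(GenomicRanges::seqnames(genes))[i],
      gene5pBoundary(genes)[i],
      as.character(GenomicRanges::strand(genes))[i],
      0L, GenomicRanges::width(genes)[i] - 1L)
  }, character(1))
  names(cds) <- genes$gene_id
  ok <- !is.na(cds) & nchar(cds) %% 3 == 0
  if (any(!ok)) {
    warning("skipping gene(s) with length not a multiple of 3: ",
      paste(genes$gene_id[!ok], collapse = ", "))
  }
  codonsOf <- function(s) substring(s, seq(1, nchar(s) - 2, 3), seq(3, nchar(s), 3))
  allCodons <- names(Biostrings::GENETIC_CODE)
  refIds <- intersect(referenceSet, names(cds)[ok])
  if (!length(refIds)) stop("no usable reference genes")
  refCounts <- table(factor(unlist(lapply(cds[refIds], codonsOf)),
    levels = allCodons)) + 0.5
  fam <- caiCodonFamilies()
  w <- stats::setNames(rep(NA_real_, length(allCodons)), allCodons)
  for (f in fam) w[f] <- refCounts[f] / max(refCounts[f])
  rows <- lapply(which(ok), function(i) {
    cod <- codonsOf(cds[i])
    wi <- w[cod]
    wi <- wi[!is.na(wi)] # drops stops, Met, Trp, N-containing codons
    chars <- strsplit(cds[i], "")[[1]]
    data.frame(gene_id = names(cds)[i],
      cai = if (length(wi)) exp(mean(log(wi))) else NA_real_,
      gc = mean(chars %in% c("G", "C")))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "w") <- w
  out
}
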