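## Independent brute-force oracles and small fixture builders used across
## the suite. The oracles apply the rules literally on dense vectors and
## share no code with the package implementations.

## literal consensus-end rule: dense per-position vectors, peaks as runs of
## nonzero summed signal with gaps <= mergeWindow bridged, per-replicate
## argmax, identical-position support count, mean-CPM filter
bruteConsensusEnds <- function(mats, strand, minReplicates = 3, minCpm = 5,
                               mergeWindow = 3) {
  summed <- Reduce(`+`, mats)
  L <- length(summed)
  nz <- which(summed > 0)
  if (!length(nz)) return(integer(0))
  peaks <- list()
  cur <- nz[1]
  for (p in nz[-1]) {
    if (p - cur[length(cur)] <= mergeWindow + 1) cur <- c(cur, p)
    else { peaks[[length(peaks) + 1]] <- cur; cur <- p }
  }
  peaks[[length(peaks) + 1]] <- cur
  calls <- integer(0)
  heights <- numeric(0)
  for (pk in peaks) {
    span <- min(pk):max(pk)
    am <- sapply(mats, function(m) {
      v <- m[span]
      if (all(v == 0)) return(NA_integer_)
      cand <- span[v == max(v)]
      if (strand == "+") min(cand) else max(cand)
    })
    for (pos in unique(am[!is.na(am)])) {
      sup <- which(!is.na(am) & am == pos)
      if (length(sup) < minReplicates) next
      h <- mean(sapply(mats[sup], function(m) m[pos]))
      if (h < minCpm) next
      calls <- c(calls, pos)
      heights <- c(heights, h)
    }
  }
  o <- order(calls)
  data.frame(position = calls[o], height = heights[o])
}

## dense random CPM-scaled replicate tracks on a short contig
randomTrackSet <- function(L = 2000, nRep = 4, nPeaks = 8, seed = 1) {
  set.seed(seed)
  centers <- sort(sample(10:(L - 10), nPeaks))
  mats <- lapply(seq_len(nRep), function(r) {
    m <- numeric(L)
    for (ctr in centers) {
      n <- rpois(1, 30)
      if (n == 0) next
      p <- pmin(pmax(ctr + round(rnorm(n, 0, 1.2)), 1), L)
      tb <- table(p)
      m[as.integer(names(tb))] <- m[as.integer(names(tb))] + as.numeric(tb)
    }
    nbg <- rpois(1, 3)
    if (nbg > 0) {
      p <- sample.int(L, nbg)
      m[p] <- m[p] + 1
    }
    m * 1e6 / max(1, sum(m)) # CPM within the track
  })
  mats
}

trackFromDense <- function(m, strand, contig = "c1") {
  endTrack(contig, strand, which(m > 0), m[m > 0], length(m),
    libraryTotal = 1, normalized = "cpm")
}

## step-up BH by the definition (sort, scale, cummin from the right)
bruteBH <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

## Wallenius upper tail by explicit enumeration of all draw orderings
## (feasible for nTotal <= 12): each ordering is a binary sequence of
## category/non-category draws with probability given by the sequential
## weighted-urn products
enumWalleniusTail <- function(x, nCat, nDe, nTotal, odds) {
  probTail <- 0
  recurse <- function(drawn, reds, prob) {
    if (drawn == nDe) {
      if (reds >= x) probTail <<- probTail + prob
      return(invisible())
    }
    rRem <- nCat - reds
    wRem <- (nTotal - nCat) - (drawn - reds)
    tot <- odds * rRem + wRem
    if (rRem > 0) recurse(drawn + 1, reds + 1, prob * odds * rRem / tot)
    if (wRem > 0) recurse(drawn + 1, reds, prob * wRem / tot)
  }
  recurse(0, 0, 1)
  probTail
}

## exhaustive PWM score tail: enumerate all 4^L sequences
enumPwmTail <- function(pwm, obsScore) {
  sc <- pwmScores(pwm)
  bg <- pwmBackground(pwm)
  L <- ncol(sc)
  grid <- as.matrix(expand.grid(rep(list(1:4), L)))
  scores <- rowSums(matrix(sc[cbind(as.vector(grid),
    rep(seq_len(L), each = nrow(grid)))], nrow(grid)))
  probs <- apply(matrix(bg[grid], nrow(grid)), 1, prod)
  function(thr) sum(probs[scores >= thr])
}

randomPwm <- function(L, seed) {
  set.seed(seed)
  probs <- matrix(rgamma(4 * L, 1), 4)
  probs <- sweep(probs, 2, colSums(probs), "/")
  rownames(probs) <- c("A", "C", "G", "T")
  bg <- rgamma(4, 2)
  bg <- bg / sum(bg)
  methods::new("MotifPWM", probs = probs,
    scores = log2(probs / bg), background = bg, pseudocount = 0)
}

## small annotated genome fixture without the full generator
tinyGenome <- function(seq = NULL, len = 12000) {
  if (is.null(seq)) {
    set.seed(99)
    seq <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
      prob = c(0.3, 0.2, 0.2, 0.3)), collapse = "")
  }
  g <- Biostrings::DNAStringSet(seq)
  names(g) <- "c1"
  g
}

adjustedRand <- function(a, b) mclust::adjustedRandIndex(a, b)
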