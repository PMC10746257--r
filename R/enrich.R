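## Length-bias-aware category enrichment: a monotone probability weighting
## function (PWF) of gene length fitted by binned isotonic regression, and
## Wallenius noncentral hypergeometric tail probabilities computed by
## numerical integration of the exact density.

## weighted pool-adjacent-violators for a nondecreasing fit
pavaNondecreasing <- function(y, w) {
  n <- length(y)
  val <- y; wt <- w; idx <- rep(1:n, 1)
  i <- 1L
  vals <- numeric(0); wts <- numeric(0); sizes <- integer(0)
  for (i in seq_len(n)) {
    vals <- c(vals, y[i]); wts <- c(wts, w[i]); sizes <- c(sizes, 1L)
    k <- length(vals)
    while (k > 1L && vals[k - 1L] > vals[k]) {
      newW <- wts[k - 1L] + wts[k]
      vals[k - 1L] <- (vals[k - 1L] * wts[k - 1L] + vals[k] * wts[k]) / newW
      wts[k - 1L] <- newW
      sizes[k - 1L] <- sizes[k - 1L] + sizes[k]
      vals <- vals[-k]; wts <- wts[-k]; sizes <- sizes[-k]
      k <- k - 1L
    }
  }
  rep(vals, sizes)
}

#' Fit a probability weighting function of gene length
#'
#' Genes are binned by length quantiles; the per-bin fraction of
#' differentially expressed genes is made monotone nondecreasing in length
#' by pool-adjacent-violators, interpolated back to each gene's length,
#' floored at 1e-6 and rescaled to mean 1.
#'
#' @param deIndicator 0/1 (or logical) per gene.
#' @param lengths gene lengths in nt.
#' @param nBins number of quantile bins (default 20).
#' @return numeric vector of per-gene weights (mean 1); bin fit in
#'   attribute `"bins"`. Constant lengths give a flat PWF with a warning.
#' @export
fitPwf <- function(deIndicator, lengths, nBins = 20L) {
  de <- as.numeric(deIndicator)
  stopifnot(length(de) == length(lengths), all(de %in% c(0, 1)))
  if (sum(de) == 0 || sum(de) == length(de))
    stop("need at least one DE and one non-DE gene")
  if (length(unique(lengths)) == 1L) {
    warning("constant gene lengths: flat PWF")
    return(rep(1, length(de)))
  }
  br <- unique(stats::quantile(lengths, probs = seq(0, 1, length.out = nBins + 1)))
  bin <- cut(lengths, br, include.lowest = TRUE)
  frac <- tapply(de, bin, mean)
  cnt <- as.numeric(table(bin))
  mid <- tapply(lengths, bin, mean)
  keep <- cnt > 0
  fit <- pavaNondecreasing(as.numeric(frac[keep]), cnt[keep])
  w <- stats::approx(as.numeric(mid[keep]), fit, xout = lengths, rule = 2)$y
  w <- pmax(w, 1e-6)
  w <- w / mean(w)
  attr(w, "bins") <- data.frame(mid = as.numeric(mid[keep]), fit = fit,
    n = cnt[keep])
  w
}

## exact Wallenius pmf over the whole support, by the sequential-draw
## recursion: at each draw a remaining category item (weight omega) is
## taken with probability omega*r / (omega*r + w), where r and w count the
## remaining category / non-category items
walleniusPmf <- function(m1, m2, nDraw, omega) {
  p <- c(1, rep(0, min(m1, nDraw))) # p[x + 1] = P(x reds after k draws)
  for (k in seq_len(nDraw)) {
    xmax <- min(m1, k - 1L)
    x <- 0:xmax
    wRem <- m2 - ((k - 1L) - x) # remaining non-category items
    rRem <- m1 - x
    tot <- omega * rRem + wRem
    pRed <- ifelse(tot > 0, omega * rRem / tot, 0)
    pWhite <- ifelse(tot > 0, wRem / tot, 0)
    np <- numeric(length(p))
    np[x + 1L] <- p[x + 1L] * pWhite
    up <- x + 2L
    keep <- up <= length(np)
    np[up[keep]] <- np[up[keep]] + p[x + 1L][keep] * pRed[keep]
    p <- np
  }
  p / sum(p)
}

#' Wallenius noncentral hypergeometric upper tail
#'
#' Probability of drawing at least `x` category genes when `nDe` genes are
#' drawn without replacement from `nTotal`, of which `nCat` belong to the
#' category and carry sampling weight `odds` relative to the rest. The
#' probability mass is evaluated exactly over the whole support by the
#' sequential-draw recursion and normalized before summing the tail.
#'
#' @param x observed category count (tail from `x` upward).
#' @param nCat category size.
#' @param nDe number of draws (DE genes).
#' @param nTotal background size.
#' @param odds weight ratio category/non-category (> 0); 1 recovers the
#'   central hypergeometric distribution.
#' @return `P(X >= x)`.
#' @examples
#' walleniusTail(3, 5, 8, 20, 1) # equals phyper(2, 5, 15, 8, lower.tail = FALSE)
#' @export
walleniusTail <- function(x, nCat, nDe, nTotal, odds) {
  if (odds <= 0) stop("odds must be positive")
  stopifnot(nCat >= 0, nDe >= 0, nTotal >= nCat, nDe <= nTotal)
  m1 <- nCat
  m2 <- nTotal - nCat
  supp <- max(0L, nDe - m2):min(m1, nDe)
  if (x <= min(supp)) return(1)
  if (x > max(supp)) return(0)
  pm <- walleniusPmf(m1, m2, nDe, odds)
  sum(pm[(0:min(m1, nDe)) >= x])
}

#' Length-bias-corrected category enrichment
#'
#' goseq-style test: the DE set is all genes regulated in the requested
#' direction (strong and moderate alike); a PWF is fitted to the DE
#' indicator versus gene length; each category's odds is the mean PWF
#' weight inside the category divided by the mean outside; the p-value is
#' the Wallenius noncentral hypergeometric upper tail. No multiple-testing
#' correction is applied by default (raw p thresholded at `alpha`), with
#' an optional BH adjustment.
#'
#' @param groups per-gene regulation group (from [classifyRegulation()])
#'   over the detected background.
#' @param categories per-gene category code (`NA` = unassigned).
#' @param lengths per-gene lengths in nt.
#' @param direction `"up"` (strong_up + up) or `"down"`.
#' @param alpha significance threshold on the raw p-value (default 0.05).
#' @param adjust apply BH across categories (default FALSE).
#' @return data.frame `category`, `direction`, `n_de_in_cat`, `n_cat`,
#'   `n_de`, `n_total`, `odds`, `p`, (`padj`,) `significant`, ordered by
#'   p.
#' @export
arcogEnrichment <- function(groups, categories, lengths,
                            direction = c("up", "down"), alpha = 0.05,
                            adjust = FALSE) {
  direction <- match.arg(direction)
  wanted <- if (direction == "up") c("up", "strong_up") else c("down", "strong_down")
  de <- as.integer(groups %in% wanted)
  if (sum(de) == 0)
    stop("no genes regulated in direction '", direction,
      "': empty test")
  w <- fitPwf(de, lengths)
  nTotal <- length(de)
  nDe <- sum(de)
  cats <- sort(unique(categories[!is.na(categories)]))
  rows <- lapply(cats, function(cc) {
    inCat <- !is.na(categories) & categories == cc
    nCat <- sum(inCat)
    if (nCat == 0L) return(NULL)
    odds <- mean(w[inCat]) / mean(w[!inCat])
    xObs <- sum(de[inCat])
    p <- walleniusTail(xObs, nCat, nDe, nTotal, odds)
    data.frame(category = cc, direction = direction,
      n_de_in_cat = xObs, n_cat = nCat, n_de = nDe, n_total = nTotal,
      odds = odds, p = p)
  })
  out <- do.call(rbind, rows)
  if (adjust) {
    out$padj <- bhAdjust(out$p)
    out$significant <- out$padj < alpha
  } else {
    out$significant <- out$p < alpha
  }
  out[order(out$p), , drop = FALSE]
}
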