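## Simplified differential tests for RNA counts (negative-binomial Wald)
## and protein intensities (moderated t), plus TPM, median-of-ratios size
## factors, BH adjustment and the five-level regulation grouping.

#' Transcripts-per-million normalization
#'
#' Reads per kilobase (counts divided by gene length in kb), rescaled per
#' sample so the column sums are one million.
#'
#' @param rna an RNA [OmicsExperiment-class] with gene lengths.
#' @return TPM matrix (genes x samples). All-zero samples stay all-zero
#'   (with a warning).
#' @examples
#' m <- matrix(c(10, 40), 2, 1, dimnames = list(c("a", "b"), "s1"))
#' oe <- omicsExperiment(m, "Ctrl", 1, "rna", lengths = c(1000, 2000))
#' tpmNormalize(oe) # 333333.3 / 666666.7
#' @export
tpmNormalize <- function(rna) {
  stopifnot(is(rna, "OmicsExperiment"), omicsKind(rna) == "rna")
  lens <- geneLengths(rna)
  if (any(lens <= 0)) stop("zero or negative gene length")
  counts <- SummarizedExperiment::assay(rna)
  rpk <- counts / (lens / 1000)
  tot <- colSums(rpk)
  if (any(tot == 0)) warning("all-zero sample(s): TPM left at 0")
  tot[tot == 0] <- 1
  sweep(rpk, 2, tot, "/") * 1e6
}

#' Median-of-ratios size factors
#'
#' For each sample, the median over genes of the ratio of the gene's count
#' to its geometric mean across samples, restricted to genes with strictly
#' positive counts everywhere; factors are rescaled to geometric mean 1.
#'
#' @param counts count matrix or RNA [OmicsExperiment-class].
#' @return named numeric vector of per-sample factors.
#' @export
sizeFactors <- function(counts) {
  if (is(counts, "OmicsExperiment")) counts <- SummarizedExperiment::assay(counts)
  counts <- as.matrix(counts)
  if (ncol(counts) == 1L) return(stats::setNames(1, colnames(counts)))
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos))
    stop("no gene with positive counts in every sample; ",
      "consider adding a pseudocount")
  lg <- log(counts[pos, , drop = FALSE])
  geo <- rowMeans(lg)
  sf <- exp(apply(lg - geo, 2, stats::median))
  sf <- sf / exp(mean(log(sf)))
  stats::setNames(sf, colnames(counts))
}

#' Negative-binomial Wald test for RNA counts, one condition vs control
#'
#' Counts are scaled by median-of-ratios size factors. Per gene, the log2
#' fold change is `log2((mean_cond + 0.5) / (mean_ctrl + 0.5))`; an NB
#' dispersion is estimated by method of moments pooled across the two
#' conditions (floored at 1e-8) and propagated to a delta-method standard
#' error of the log2 fold change. The Wald statistic is referred to a t
#' distribution with `n1 + n2 - 2` degrees of freedom, which keeps the
#' test close to nominal size at a handful of replicates.
#'
#' @param rna RNA [OmicsExperiment-class].
#' @param condition condition to compare against the control.
#' @param ctrl control condition label (default `"Ctrl"`).
#' @param sf optional size factors for all samples (default: computed from
#'   the full matrix).
#' @param keep optional logical per sample (outlier removal); must leave
#'   at least 2 replicates per condition.
#' @return data.frame `gene_id`, `contrast`, `log2FC`, `p`; genes with no
#'   counts in either condition are omitted.
#' @seealso [bhAdjust()], [classifyRegulation()], [deAnalysis()]
#' @export
rnaDeTest <- function(rna, condition, ctrl = "Ctrl", sf = NULL, keep = NULL) {
  stopifnot(is(rna, "OmicsExperiment"), omicsKind(rna) == "rna")
  counts <- SummarizedExperiment::assay(rna)
  cond <- omicsConditions(rna)
  if (is.null(sf)) sf <- sizeFactors(counts)
  if (is.null(keep)) keep <- rep(TRUE, ncol(counts))
  i1 <- which(cond == condition & keep)
  i0 <- which(cond == ctrl & keep)
  if (length(i1) < 2L || length(i0) < 2L)
    stop("need at least 2 replicates per condition")
  y <- sweep(counts, 2, sf, "/")
  y1 <- y[, i1, drop = FALSE]
  y0 <- y[, i0, drop = FALSE]
  m1 <- rowMeans(y1)
  m0 <- rowMeans(y0)
  present <- m1 > 0 | m0 > 0
  n1 <- length(i1); n0 <- length(i0)
  c0 <- 0.5
  l2fc <- log2((m1 + c0) / (m0 + c0))
  s2 <- (rowSums((y1 - m1)^2) + rowSums((y0 - m0)^2)) / (n1 + n0 - 2)
  mbar <- (n1 * m1 + n0 * m0) / (n1 + n0)
  disp <- pmax(1e-8, (s2 - mbar) / mbar^2)
  v1 <- (m1 + disp * m1^2) / n1
  v0 <- (m0 + disp * m0^2) / n0
  se <- sqrt(v1 / (m1 + c0)^2 + v0 / (m0 + c0)^2) / log(2)
  stat <- ifelse(se > 0, l2fc / se, 0)
  p <- 2 * stats::pt(-abs(stat), df = n1 + n0 - 2)
  p[l2fc == 0] <- 1
  data.frame(
    gene_id = rownames(counts)[present],
    contrast = paste0(condition, "_vs_", ctrl),
    log2FC = l2fc[present], p = p[present], row.names = NULL
  )
}

## solve trigamma(x) = y (limma-style Newton iteration)
trigammaInverse <- function(y) {
  vapply(y, function(t) {
    if (t <= 0) return(Inf)
    if (t > 1e7) return(1 / sqrt(t))
    x <- 0.5 + 1 / t
    for (iter in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / t) / psigamma(x, 2)
      x <- x + dif
      if (-dif / x < 1e-8) break
    }
    x
  }, numeric(1))
}

#' Moderated t-test for protein intensities, one condition vs control
#'
#' Intensities are upper-quartile normalized (each sample scaled so the
#' 75th percentile of its observed values matches the geometric mean of
#' the per-sample 75th percentiles), log2-transformed, and compared by a
#' two-sample t-statistic with empirical-Bayes variance moderation: the
#' prior `(d0, s0^2)` is fitted by moment matching on the distribution of
#' log sample variances, the posterior variance is
#' `(d0 s0^2 + d s^2) / (d0 + d)`, and p-values come from a t distribution
#' with `d0 + d` degrees of freedom.
#'
#' @param protein protein [OmicsExperiment-class] (`NA` = not detected).
#' @param condition condition to compare against the control.
#' @param ctrl control condition label.
#' @param keep optional logical per sample (outlier removal).
#' @return data.frame `gene_id`, `contrast`, `log2FC`, `p`; genes observed
#'   in fewer than 2 samples in either group are omitted. The fitted prior
#'   is in attributes `"d0"` and `"s0sq"`.
#' @export
proteinDeTest <- function(protein, condition, ctrl = "Ctrl", keep = NULL) {
  stopifnot(is(protein, "OmicsExperiment"), omicsKind(protein) == "protein")
  x <- SummarizedExperiment::assay(protein)
  if (any(x[!is.na(x)] <= 0)) stop("intensities must be positive where observed")
  q75 <- apply(x, 2, stats::quantile, 0.75, na.rm = TRUE)
  x <- sweep(x, 2, exp(mean(log(q75))) / q75, "*")
  lx <- log2(x)
  cond <- omicsConditions(protein)
  if (is.null(keep)) keep <- rep(TRUE, ncol(x))
  i1 <- which(cond == condition & keep)
  i0 <- which(cond == ctrl & keep)
  x1 <- lx[, i1, drop = FALSE]
  x0 <- lx[, i0, drop = FALSE]
  n1 <- rowSums(!is.na(x1))
  n0 <- rowSums(!is.na(x0))
  ok <- n1 >= 2L & n0 >= 2L
  m1 <- rowMeans(x1, na.rm = TRUE)
  m0 <- rowMeans(x0, na.rm = TRUE)
  ss <- rowSums((x1 - m1)^2, na.rm = TRUE) + rowSums((x0 - m0)^2, na.rm = TRUE)
  d <- n1 + n0 - 2L
  s2 <- ifelse(ok & d > 0, ss / d, NA)
  ## moment matching of the scaled-F model on log s^2, at the modal df
  dmode <- as.integer(names(which.max(table(d[ok & s2 > 0]))))
  zi <- log(s2[ok & s2 > 0 & d == dmode])
  e <- zi - digamma(dmode / 2) + log(dmode / 2)
  evar <- stats::var(e) - trigamma(dmode / 2)
  if (length(zi) >= 10L && is.finite(evar) && evar > 0) {
    d0 <- 2 * trigammaInverse(evar)
    s0sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0sq <- mean(exp(zi))
  }
  post <- if (is.finite(d0)) (d0 * s0sq + d * s2) / (d0 + d) else s0sq
  se <- sqrt(post * (1 / n1 + 1 / n0))
  stat <- (m1 - m0) / se
  df <- d0 + d
  p <- 2 * stats::pt(-abs(stat), df = pmin(df, 1e6))
  out <- data.frame(
    gene_id = rownames(x)[ok],
    contrast = paste0(condition, "_vs_", ctrl),
    log2FC = (m1 - m0)[ok], p = p[ok], row.names = NULL
  )
  attr(out, "d0") <- d0
  attr(out, "s0sq") <- s0sq
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' order-preserving.
#'
#' @param p numeric p-values in `[0, 1]`.
#' @return adjusted p-values in the input order.
#' @export
bhAdjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Five-level regulation grouping
#'
#' RNA: `strong_up` (padj < 0.05 and log2FC >= 1), `up` (padj < 0.05 and
#' 0 < log2FC < 1), `strong_down` (padj < 0.05 and log2FC <= -1), `down`
#' (padj < 0.05 and -1 < log2FC < 0), otherwise `ns`. Protein uses no fold
#' change threshold: `up`/`down` for any significant positive/negative
#' log2FC.
#'
#' @param log2FC,padj numeric vectors.
#' @param kind `"rna"` or `"protein"`.
#' @return character vector of group labels.
#' @examples
#' classifyRegulation(c(5.4, 0.5, -1), c(1e-6, 0.2, 0.01), "rna")
#' @export
classifyRegulation <- function(log2FC, padj, kind = c("rna", "protein")) {
  kind <- match.arg(kind)
  stopifnot(all(padj >= 0 & padj <= 1, na.rm = TRUE))
  sig <- !is.na(padj) & padj < 0.05
  out <- rep("ns", length(log2FC))
  if (kind == "rna") {
    out[sig & log2FC >= 1] <- "strong_up"
    out[sig & log2FC > 0 & log2FC < 1] <- "up"
    out[sig & log2FC <= -1] <- "strong_down"
    out[sig & log2FC < 0 & log2FC > -1] <- "down"
  } else {
    out[sig & log2FC > 0] <- "up"
    out[sig & log2FC < 0] <- "down"
  }
  out
}

#' Run all pairwise contrasts against the control and group genes
#'
#' Applies [rnaDeTest()] or [proteinDeTest()] for every non-control
#' condition, adjusts p-values per contrast with [bhAdjust()] and labels
#' each record with [classifyRegulation()].
#'
#' @param omics an [OmicsExperiment-class].
#' @param contrasts conditions to test (default: all non-control).
#' @param ctrl control label.
#' @param keep optional logical per sample (see [flagOutliers()]).
#' @return data.frame `gene_id`, `contrast`, `log2FC`, `p`, `padj`,
#'   `group`.
#' @export
deAnalysis <- function(omics, contrasts = NULL, ctrl = "Ctrl", keep = NULL) {
  cond <- omicsConditions(omics)
  if (is.null(contrasts)) contrasts <- setdiff(unique(cond), ctrl)
  fun <- if (omicsKind(omics) == "rna") rnaDeTest else proteinDeTest
  out <- lapply(contrasts, function(cc) {
    de <- fun(omics, cc, ctrl = ctrl, keep = keep)
    de$padj <- bhAdjust(de$p)
    de$group <- classifyRegulation(de$log2FC, de$padj, omicsKind(omics))
    de
  })
  do.call(rbind, out)
}
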