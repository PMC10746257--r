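## RNA/protein integration: pairwise-complete correlation, per-gene
## z-scoring of fold-change profiles, PCA + Euclidean + ward.D2 clustering
## with elbow-based k selection, cluster profile summaries and replicate
## outlier flagging.

#' Pairwise-complete Pearson correlation
#'
#' Pearson correlation between every column of `a` and every column of
#' `b`, computed over the rows where both entries are present; pairs with
#' fewer than 3 complete observations are reported as `NA`.
#'
#' @param a,b matrices with matching row (gene) index; `b` defaults to
#'   `a`.
#' @return list with matrices `r` (correlations) and `n` (complete pairs
#'   used).
#' @export
pairwiseCorrelation <- function(a, b = a) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(nrow(a) == nrow(b))
  r <- suppressWarnings(stats::cor(a, b, use = "pairwise.complete.obs"))
  n <- crossprod(!is.na(a), !is.na(b))
  r[n < 3] <- NA
  list(r = r, n = n)
}

#' Combine and z-score RNA/protein fold-change profiles per gene
#'
#' For each gene and each layer, the condition vector is centred and
#' scaled to unit variance (computed over non-missing entries). Rows with
#' zero variance or fewer than 2 observed entries in a layer are dropped
#' and reported.
#'
#' @param fc named list of genes x conditions log2 fold-change matrices
#'   (e.g. `list(rna = ..., protein = ...)`); matching row names required.
#' @return list with `z` (genes x (layer_condition) matrix of z-scores,
#'   `NA` preserved) and `dropped` (character vector of dropped gene
#'   ids).
#' @export
zscoreRows <- function(fc) {
  stopifnot(is.list(fc), length(fc) >= 1, !is.null(names(fc)))
  genes <- rownames(fc[[1]])
  zs <- lapply(names(fc), function(layer) {
    m <- as.matrix(fc[[layer]])
    stopifnot(identical(rownames(m), genes))
    mu <- rowMeans(m, na.rm = TRUE)
    sdv <- apply(m, 1, stats::sd, na.rm = TRUE)
    z <- (m - mu) / sdv
    bad <- !is.finite(sdv) | sdv == 0 | rowSums(!is.na(m)) < 2
    z[bad, ] <- NA
    colnames(z) <- paste(layer, colnames(m), sep = "_")
    list(z = z, bad = bad)
  })
  z <- do.call(cbind, lapply(zs, `[[`, "z"))
  badAny <- Reduce(`|`, lapply(zs, `[[`, "bad"))
  list(z = z[!badAny, , drop = FALSE], dropped = genes[badAny])
}

#' Cluster gene profiles by PCA, Euclidean distance and ward.D2
#'
#' Missing z-scores are zero-imputed (genes missing more than
#' `maxMissing` of their features are dropped first); principal components
#' are computed by singular value decomposition, keeping (`nPcs =
#' "auto"`) the smallest number of components explaining at least 90% of
#' the variance; Euclidean distances between gene scores feed
#' agglomerative clustering with the ward.D2 criterion. The number of
#' clusters is the elbow of the within-cluster sum of squares over
#' `kRange` (maximal second difference, interior points); the full curve
#' is returned so callers can override `k`.
#'
#' @param z z-score matrix from [zscoreRows()].
#' @param kRange candidate cluster numbers (default 2:8).
#' @param nPcs `"auto"` or an integer number of components.
#' @param k optional override of the elbow choice.
#' @param maxMissing maximum tolerated fraction of missing features per
#'   gene (default 0.5).
#' @return list with `assignment` (named integer vector), `k`, `elbow`
#'   (data.frame `k`, `wss`), `nPcs`, `varExplained`, `nImputed`,
#'   `scores`, and the `hclust` tree.
#' @export
clusterGenes <- function(z, kRange = 2:8, nPcs = "auto", k = NULL,
                         maxMissing = 0.5) {
  if (!length(kRange)) stop("empty kRange")
  miss <- rowMeans(is.na(z))
  z <- z[miss <= maxMissing, , drop = FALSE]
  kRange <- kRange[kRange >= 2 & kRange <= nrow(z) - 1]
  if (!length(kRange)) stop("kRange outside [2, n_genes - 1]")
  nImputed <- sum(is.na(z))
  z[is.na(z)] <- 0
  sv <- svd(z)
  varExpl <- cumsum(sv$d^2) / sum(sv$d^2)
  keep <- if (identical(nPcs, "auto")) which(varExpl >= 0.9)[1]
    else min(as.integer(nPcs), length(sv$d))
  scores <- sv$u[, seq_len(keep), drop = FALSE] %*%
    diag(sv$d[seq_len(keep)], nrow = keep)
  rownames(scores) <- rownames(z)
  d <- stats::dist(scores)
  hc <- stats::hclust(d, method = "ward.D2")
  if (any(diff(hc$height) < -1e-8))
    warning("non-monotone merge heights in ward.D2 tree")
  wss <- vapply(kRange, function(kk) {
    cl <- stats::cutree(hc, k = kk)
    sum(vapply(split(seq_len(nrow(scores)), cl), function(ix) {
      sc <- scores[ix, , drop = FALSE]
      sum(sweep(sc, 2, colMeans(sc))^2)
    }, numeric(1)))
  }, numeric(1))
  elbow <- data.frame(k = kRange, wss = wss)
  if (is.null(k)) {
    if (length(kRange) >= 3) {
      d2 <- wss[1:(length(wss) - 2)] - 2 * wss[2:(length(wss) - 1)] +
        wss[3:length(wss)]
      k <- kRange[which.max(d2) + 1L]
    } else {
      k <- kRange[1]
    }
  }
  assignment <- stats::cutree(hc, k = k)
  list(assignment = assignment, k = k, elbow = elbow,
    nPcs = keep, varExplained = varExpl[keep], nImputed = nImputed,
    scores = scores, tree = hc)
}

#' Median/IQR condition profiles per cluster
#'
#' @param assignment named cluster labels from [clusterGenes()].
#' @param z z-score matrix (the clustering input); columns are
#'   `layer_condition` features.
#' @return data.frame `cluster`, `feature`, `median`, `iqr`, `n`.
#' @export
clusterProfiles <- function(assignment, z) {
  z <- z[names(assignment), , drop = FALSE]
  rows <- lapply(sort(unique(assignment)), function(cl) {
    sub <- z[assignment == cl, , drop = FALSE]
    data.frame(
      cluster = cl, feature = colnames(z),
      median = apply(sub, 2, stats::median, na.rm = TRUE),
      iqr = apply(sub, 2, stats::IQR, na.rm = TRUE),
      n = nrow(sub), row.names = NULL
    )
  })
  do.call(rbind, rows)
}

#' Flag outlier replicates within each condition
#'
#' Log-transformed values of each condition's replicates are projected on
#' the first two principal components; each replicate's Euclidean distance
#' to the condition centroid is converted to a modified z-score (excess
#' over the median distance, scaled by the median absolute deviation of
#' the distances) and the replicate is flagged when that score exceeds
#' `c` (3.5 is the classical robust-outlier cutoff). Flags are advisory:
#' the caller decides removal.
#'
#' @param omics an [OmicsExperiment-class].
#' @param c flagging multiplier (default 3.5).
#' @return named logical vector per sample; conditions with fewer than 3
#'   replicates yield no flags (with a warning).
#' @export
flagOutliers <- function(omics, c = 3.5) {
  x <- SummarizedExperiment::assay(omics)
  cond <- omicsConditions(omics)
  flags <- stats::setNames(rep(FALSE, ncol(x)), colnames(x))
  for (cc in unique(cond)) {
    idx <- which(cond == cc)
    if (length(idx) < 3L) {
      warning("condition '", cc, "' has < 3 replicates; no flags")
      next
    }
    sub <- log2(x[, idx, drop = FALSE] + 1)
    sub <- sub[stats::complete.cases(sub), , drop = FALSE]
    if (nrow(sub) < 2L) next
    pc <- stats::prcomp(t(sub), rank. = 2L)
    sc <- pc$x[, seq_len(min(2L, ncol(pc$x))), drop = FALSE]
    dctr <- sqrt(rowSums(sweep(sc, 2, colMeans(sc))^2))
    m <- stats::mad(dctr)
    if (m > 0) flags[idx] <- (dctr - stats::median(dctr)) / m > c
  }
  flags
}
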