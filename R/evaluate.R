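#' Score called 3' ends against planted truth
#'
#' Greedy one-to-one matching of calls to planted ends on the same strand
#' within `tol` nt (nearest first); precision/recall/F1 over the matched
#' pairs, plus the fraction of matched calls whose
#' primary/secondary/internal class equals the planted class.
#'
#' @param calls classified calls from [classifyEnds()].
#' @param truth truth list from [makeGenomeAnnotation()].
#' @param tol matching tolerance in nt (use 0 in noise-free settings).
#' @return list `tp`, `fp`, `fn`, `precision`, `recall`, `f1`,
#'   `class_accuracy`.
#' @export
scoreEndRecovery <- function(calls, truth, tol = 3L) {
  tg <- truth$genes
  te <- rbind(
    data.frame(pos = tg$primary_pos, strand = tg$strand, class = "primary"),
    data.frame(pos = tg$secondary_pos, strand = tg$strand, class = "secondary"),
    data.frame(pos = tg$internal_pos, strand = tg$strand, class = "internal")
  )
  te <- te[!is.na(te$pos), , drop = FALSE]
  used <- rep(FALSE, nrow(te))
  tp <- 0L
  classOK <- 0L
  for (i in seq_len(nrow(calls))) {
    d <- abs(te$pos - calls$position[i])
    j <- which(te$strand == calls$strand[i] & d <= tol & !used)
    if (!length(j)) next
    j <- j[which.min(d[j])]
    used[j] <- TRUE
    tp <- tp + 1L
    if (te$class[j] == calls$end_class[i]) classOK <- classOK + 1L
  }
  fp <- nrow(calls) - tp
  fn <- nrow(te) - tp
  precision <- if (tp + fp) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn) tp / (tp + fn) else NA_real_
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0)
    NA_real_ else 2 * precision * recall / (precision + recall)
  list(tp = tp, fp = fp, fn = fn, precision = precision, recall = recall,
    f1 = f1, class_accuracy = if (tp) classOK / tp else NA_real_)
}

#' Mirror gene models onto the reverse-complemented genome
#'
#' Maps every gene to its coordinates on the strand-mirrored genome
#' (position p becomes L + 1 - p, strands swap); useful for
#' strand-symmetry checks together with [mirrorGenome()].
#'
#' @param genes gene `GRanges`.
#' @param len contig length.
#' @return the mirrored gene `GRanges`.
#' @export
mirrorGenes <- function(genes, len) {
  geneModels(
    gene_id = genes$gene_id,
    contig = as.character(GenomicRanges::seqnames(genes)),
    start = mirrorPosition(GenomicRanges::end(genes), len),
    end = mirrorPosition(GenomicRanges::start(genes), len),
    strand = mirrorStrand(as.character(GenomicRanges::strand(genes))),
    tss = ifelse(is.na(genes$tss), NA_integer_,
      mirrorPosition(genes$tss, len)),
    utr5_len = genes$utr5_len,
    arcog = genes$arcog
  )
}
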