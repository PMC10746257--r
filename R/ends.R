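## Term-seq 3'-end pipeline: CPM normalization, replicate-consensus peak
## calling, classification relative to genes, 3'-UTR lengths, and long-read
## transcriptional-unit calling.

#' CPM-normalize an end-count track
#'
#' Scales every per-position count by `1e6 / libraryTotal`, where the
#' library total is the raw end count of the whole replicate (both
#' strands), so the CPM values of a replicate's paired tracks sum to one
#' million.
#'
#' @param track a raw [EndTrack-class].
#' @param libraryTotal total raw end count of the replicate; defaults to
#'   the total recorded in the track.
#' @return the CPM-scaled [EndTrack-class].
#' @examples
#' tr <- endTrack("c1", "+", c(1L, 2L, 3L), c(10, 30, 60), 100L)
#' sum(trackCounts(cpmNormalize(tr))) # 1e6
#' @export
cpmNormalize <- function(track, libraryTotal = NULL) {
  stopifnot(is(track, "EndTrack"))
  if (isNormalized(track)) stop("track is already CPM-normalized")
  total <- if (is.null(libraryTotal)) track@libraryTotal else libraryTotal
  if (!is.numeric(total) || total <= 0) stop("library total must be positive")
  endTrack(track@contig, track@strand, track@pos,
    track@count * 1e6 / total, track@contigLength,
    libraryTotal = total, normalized = "cpm")
}

#' Call consensus 3' ends across replicates
#'
#' Peaks are maximal runs of nonzero positions in the replicate-summed CPM
#' track, with gaps of up to `mergeWindow` zero positions bridged. Within
#' each peak the per-replicate maximum position is determined (ties broken
#' toward the transcript-proximal side: lowest coordinate on `+`, highest
#' on `-`). A consensus end is emitted at a position that is the maximum in
#' at least `minReplicates` replicates and whose mean CPM over those
#' supporting replicates is at least `minCpm`.
#'
#' @param tracks list of CPM-scaled [EndTrack-class]s, one per replicate,
#'   all on the same contig and strand.
#' @param minReplicates minimum replicates sharing the identical maximum
#'   position (default 3).
#' @param minCpm minimum mean CPM over supporting replicates (default 5).
#' @param mergeWindow largest zero-gap (nt) bridged inside a peak
#'   (default 3).
#' @return data.frame with one row per consensus end: `contig`, `strand`,
#'   `position`, `height` (mean CPM over supporting replicates),
#'   `n_supporting`, `peak_start`, `peak_end`.
#' @export
callConsensusEnds <- function(tracks, minReplicates = 3L, minCpm = 5,
                              mergeWindow = 3L) {
  stopifnot(length(tracks) >= 1L)
  contig <- trackContig(tracks[[1]])
  strand <- trackStrand(tracks[[1]])
  for (tr in tracks) {
    if (trackContig(tr) != contig || trackStrand(tr) != strand)
      stop("all tracks must share one contig and strand")
    if (!isNormalized(tr)) stop("tracks must be CPM-normalized")
  }
  if (length(tracks) < minReplicates)
    stop("need at least 'minReplicates' replicate tracks")
  empty <- data.frame(contig = character(), strand = character(),
    position = integer(), height = numeric(), n_supporting = integer(),
    peak_start = integer(), peak_end = integer())
  allPos <- sort(unique(unlist(lapply(tracks, trackPositions))))
  if (!length(allPos)) return(empty)
  peakId <- cumsum(c(1L, as.integer(diff(allPos) > mergeWindow + 1L)))
  lookup <- lapply(tracks, function(tr)
    stats::setNames(trackCounts(tr), trackPositions(tr)))
  proximalFirst <- function(p) if (strand == "+") sort(p) else sort(p, decreasing = TRUE)
  out <- lapply(split(allPos, peakId), function(pp) {
    argmax <- vapply(lookup, function(lk) {
      v <- lk[as.character(pp)]
      v[is.na(v)] <- 0
      if (all(v == 0)) return(NA_integer_)
      cand <- pp[v == max(v)]
      proximalFirst(cand)[1]
    }, integer(1))
    tab <- table(argmax[!is.na(argmax)])
    hits <- as.integer(names(tab)[tab >= minReplicates])
    if (!length(hits)) return(NULL)
    rows <- lapply(hits, function(h) {
      sup <- which(!is.na(argmax) & argmax == h)
      height <- mean(vapply(lookup[sup], function(lk) {
        v <- lk[as.character(h)]
        if (is.na(v)) 0 else v
      }, numeric(1)))
      if (height < minCpm) return(NULL)
      data.frame(contig = contig, strand = strand, position = h,
        height = height, n_supporting = length(sup),
        peak_start = min(pp), peak_end = max(pp))
    })
    do.call(rbind, rows)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) return(empty)
  rownames(res) <- NULL
  res[order(res$position), , drop = FALSE]
}

#' Classify consensus 3' ends relative to genes
#'
#' Ends inside a same-strand gene body are `internal`. Ends within the
#' half-open window of `downstreamWindow` nt downstream of a same-strand
#' gene's 3' boundary (in transcript orientation; the boundary itself
#' belongs to the body) are candidates for that gene; an end covered by two
#' genes' windows is assigned to the nearer gene. Per gene the
#' highest-CPM candidate is `primary` (ties broken toward the gene),
#' the remainder `secondary`; ends matching no gene are `orphan`.
#'
#' @param ends data.frame from [callConsensusEnds()] (columns `contig`,
#'   `strand`, `position`, `height`).
#' @param genes gene `GRanges`.
#' @param downstreamWindow window size in nt (default 300).
#' @return the `ends` data.frame with added `gene_id`, `end_class` and
#'   `utr3_len` (distance from the gene 3' boundary; primary ends only,
#'   otherwise `NA`).
#' @export
classifyEnds <- function(ends, genes, downstreamWindow = 300L) {
  n <- nrow(ends)
  gene_id <- rep(NA_character_, n)
  end_class <- rep("orphan", n)
  utr3 <- rep(NA_integer_, n)
  if (n == 0L) {
    return(cbind(ends, gene_id = character(), end_class = character(),
      utr3_len = integer()))
  }
  gStrand <- as.character(GenomicRanges::strand(genes))
  gContig <- as.character(GenomicRanges::seqnames(genes))
  gStart <- GenomicRanges::start(genes)
  gEnd <- GenomicRanges::end(genes)
  bnd <- gene3pBoundary(genes)
  dirv <- ifelse(gStrand == "+", 1L, -1L)
  downOff <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    same <- which(gStrand == ends$strand[i] & gContig == ends$contig[i])
    p <- ends$position[i]
    inside <- same[gStart[same] <= p & p <= gEnd[same]]
    if (length(inside)) {
      gene_id[i] <- genes$gene_id[inside[1]]
      end_class[i] <- "internal"
      next
    }
    d <- (p - bnd[same]) * dirv[same]
    cand <- same[d >= 1L & d <= downstreamWindow]
    if (length(cand)) {
      dc <- d[match(cand, same)]
      j <- cand[which.min(dc)]
      gene_id[i] <- genes$gene_id[j]
      downOff[i] <- min(dc)
      end_class[i] <- "candidate"
    }
  }
  for (g in unique(gene_id[end_class == "candidate"])) {
    idx <- which(end_class == "candidate" & gene_id == g)
    o <- idx[order(-ends$height[idx], downOff[idx])]
    end_class[o[1]] <- "primary"
    utr3[o[1]] <- downOff[o[1]]
    if (length(o) > 1L) end_class[o[-1]] <- "secondary"
  }
  out <- ends
  out$gene_id <- gene_id
  out$end_class <- end_class
  out$utr3_len <- utr3
  out
}

#' 3'-UTR lengths from primary end calls
#'
#' @param calls classified ends from [classifyEnds()].
#' @param genes gene `GRanges`.
#' @return data.frame `gene_id`, `utr3_len` (nt, signed distance from the
#'   gene 3' boundary to the primary end in transcript orientation); genes
#'   without a primary call are omitted.
#' @export
utr3Lengths <- function(calls, genes) {
  pri <- calls[calls$end_class == "primary", , drop = FALSE]
  if (nrow(pri) == 0L) return(data.frame(gene_id = character(), utr3_len = integer()))
  i <- match(pri$gene_id, genes$gene_id)
  bnd <- gene3pBoundary(genes)[i]
  dirv <- ifelse(as.character(GenomicRanges::strand(genes))[i] == "+", 1L, -1L)
  d <- (pri$position - bnd) * dirv
  stopifnot(all(d >= 0))
  data.frame(gene_id = pri$gene_id, utr3_len = as.integer(d))
}

#' Call transcriptional units from single-read intervals
#'
#' An adjacent same-strand gene pair is called co-transcribed when at least
#' `minReads` reads each overlap at least `minSpanFraction` of both genes;
#' otherwise the pair is called separate.
#'
#' @param reads data.frame of read intervals (`contig`, `start`, `end`,
#'   `strand`).
#' @param genes gene `GRanges`.
#' @param minSpanFraction minimum fraction of each gene a supporting read
#'   must cover (default 0.5).
#' @param minReads minimum number of supporting reads (default 5).
#' @return data.frame per adjacent same-strand pair (in transcript order):
#'   `up`, `down`, `n_spanning`, `unit` (`"co-transcribed"` or
#'   `"separate"`).
#' @export
callTranscriptionalUnits <- function(reads, genes, minSpanFraction = 0.5,
                                     minReads = 5L) {
  gStrand <- as.character(GenomicRanges::strand(genes))
  gContig <- as.character(GenomicRanges::seqnames(genes))
  res <- list()
  for (s in c("+", "-")) {
    for (ct in unique(gContig)) {
      idx <- which(gStrand == s & gContig == ct)
      if (length(idx) < 2L) next
      idx <- idx[order(GenomicRanges::start(genes)[idx])]
      if (s == "-") idx <- rev(idx) # transcript order
      rd <- reads[reads$strand == s & reads$contig == ct, , drop = FALSE]
      for (k in seq_len(length(idx) - 1L)) {
        i <- idx[k]; j <- idx[k + 1L]
        covFrac <- function(g) {
          ov <- pmin(rd$end, GenomicRanges::end(genes)[g]) -
            pmax(rd$start, GenomicRanges::start(genes)[g]) + 1L
          pmax(ov, 0L) / GenomicRanges::width(genes)[g]
        }
        nspan <- sum(covFrac(i) >= minSpanFraction &
          covFrac(j) >= minSpanFraction)
        res[[length(res) + 1L]] <- data.frame(
          up = genes$gene_id[i], down = genes$gene_id[j],
          n_spanning = nspan,
          unit = if (nspan >= minReads) "co-transcribed" else "separate"
        )
      }
    }
  }
  if (!length(res)) {
    return(data.frame(up = character(), down = character(),
      n_spanning = integer(), unit = character()))
  }
  do.call(rbind, res)
}
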