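#' @importFrom Biostrings DNAStringSet reverseComplement subseq
#' @importFrom GenomicRanges GRanges start end strand seqnames
#' @importFrom IRanges IRanges
NULL

BASES <- c("A", "C", "G", "T")

## transcript-orientation coordinate helpers: "downstream" of a + gene means
## increasing coordinates, of a - gene decreasing coordinates

#' Gene 3' boundary in genomic coordinates
#' @param genes a gene `GRanges`
#' @return integer vector: `end` for + genes, `start` for - genes.
#' @keywords internal
gene3pBoundary <- function(genes) {
  ifelse(as.character(GenomicRanges::strand(genes)) == "+",
    GenomicRanges::end(genes), GenomicRanges::start(genes))
}

#' Gene 5' boundary in genomic coordinates
#' @keywords internal
#' @noRd
gene5pBoundary <- function(genes) {
  ifelse(as.character(GenomicRanges::strand(genes)) == "+",
    GenomicRanges::start(genes), GenomicRanges::end(genes))
}

#' Extract a sense-strand window around an anchor position
#'
#' Offsets are in transcript orientation: offset 0 is the anchor base, +k is
#' k nt downstream (increasing coordinates on `+`, decreasing on `-`), -k is
#' k nt upstream. The returned sequence reads 5'->3' on the coding strand.
#'
#' @param genome a named [Biostrings::DNAStringSet] (see [readGenomeFasta()]).
#' @param contig contig id.
#' @param anchor 1-based anchor position.
#' @param strand `"+"` or `"-"`.
#' @param from,to signed offsets (inclusive), `from <= to`.
#' @return a character string, or `NA` if the window falls outside the
#'   contig.
#' @examples
#' g <- Biostrings::DNAStringSet(c(c1 = "AACGTT"))
#' senseWindow(g, "c1", 3, "+", -1, 1) # "ACG"
#' senseWindow(g, "c1", 3, "-", -1, 1) # "GCG" (revcomp of CGC)
#' @export
senseWindow <- function(genome, contig, anchor, strand, from, to) {
  stopifnot(from <= to)
  len <- Biostrings::width(genome)[[match(contig, names(genome))]]
  if (strand == "+") {
    lo <- anchor + from; hi <- anchor + to
  } else {
    lo <- anchor - to; hi <- anchor - from
  }
  if (lo < 1 || hi > len) return(NA_character_)
  s <- Biostrings::subseq(genome[[contig]], lo, hi)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

#' Reverse-complement mirror of a genome
#'
#' Returns the genome with every contig reverse-complemented. A feature at
#' position p on strand s maps to position `L + 1 - p` on the opposite
#' strand; useful for strand-symmetry checks.
#'
#' @param genome a named [Biostrings::DNAStringSet].
#' @return the mirrored genome.
#' @export
mirrorGenome <- function(genome) {
  Biostrings::reverseComplement(genome)
}

#' Mirror genomic positions and strands
#' @param pos integer positions, `len` contig length.
#' @param len contig length.
#' @return `len + 1 - pos`.
#' @export
mirrorPosition <- function(pos, len) len + 1L - as.integer(pos)

#' @rdname mirrorPosition
#' @param strand character vector of "+"/"-"
#' @export
mirrorStrand <- function(strand) ifelse(strand == "+", "-", "+")

#' Construct a gene-model GRanges
#'
#' Builds the `GRanges` gene container used throughout the package, with
#' metadata columns `gene_id`, optional `tss` (1-based transcription start
#' site), `utr5_len` (nt from TSS to the first coding base) and `arcog`
#' (functional category code).
#'
#' @param gene_id unique identifiers.
#' @param contig,start,end,strand 1-based inclusive gene coordinates.
#' @param tss,utr5_len,arcog optional per-gene attributes (`NA` allowed).
#' @param contigLengths optional named lengths used as `seqlengths`.
#' @return a `GRanges` sorted by coordinate.
#' @examples
#' geneModels("g1", "c1", 100, 400, "+")
#' @export
geneModels <- function(gene_id, contig, start, end, strand,
                       tss = NA_integer_, utr5_len = NA_integer_,
                       arcog = NA_character_, contigLengths = NULL) {
  if (anyDuplicated(gene_id))
    stop("duplicate gene ids: ",
      paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "))
  if (any(end < start)) stop("gene start must be <= end")
  gr <- GenomicRanges::GRanges(
    seqnames = contig,
    ranges = IRanges::IRanges(start = as.integer(start), end = as.integer(end)),
    strand = strand
  )
  S4Vectors::mcols(gr)$gene_id <- as.character(gene_id)
  S4Vectors::mcols(gr)$tss <- as.integer(rep_len(tss, length(gr)))
  S4Vectors::mcols(gr)$utr5_len <- as.integer(rep_len(utr5_len, length(gr)))
  S4Vectors::mcols(gr)$arcog <- as.character(rep_len(arcog, length(gr)))
  bad <- which(!is.na(gr$tss) &
    ((as.character(GenomicRanges::strand(gr)) == "+" &
        gr$tss > GenomicRanges::start(gr)) |
     (as.character(GenomicRanges::strand(gr)) == "-" &
        gr$tss < GenomicRanges::end(gr))))
  if (length(bad))
    stop("TSS downstream of the coding start for gene(s): ",
      paste(gr$gene_id[bad], collapse = ", "))
  if (!is.null(contigLengths))
    GenomeInfoDb::seqlengths(gr) <- contigLengths[GenomeInfoDb::seqlevels(gr)]
  sort(gr, ignore.strand = TRUE)
}

#' Intergenic intervals of an annotated genome
#'
#' Complements the gene bodies (both strands pooled) within each contig.
#'
#' @param genes gene `GRanges` from [geneModels()].
#' @param contigLengths named contig lengths.
#' @return a `GRanges` of intergenic intervals.
#' @export
intergenicIntervals <- function(genes, contigLengths) {
  gr <- GenomicRanges::GRanges(
    seqnames = GenomeInfoDb::seqlevels(genes),
    ranges = IRanges::IRanges(1L, contigLengths[GenomeInfoDb::seqlevels(genes)])
  )
  GenomicRanges::setdiff(gr, GenomicRanges::reduce(genes, ignore.strand = TRUE),
    ignore.strand = TRUE)
}
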