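## I/O for the standard formats touched by the pipeline. Internal
## coordinates are 1-based inclusive throughout (GFF3-native); the 0-based
## half-open bedGraph convention is converted at the I/O boundary only.

#' Read a genome FASTA
#'
#' @param path FASTA file (optionally gzipped).
#' @return a named [Biostrings::DNAStringSet], uppercased, one entry per
#'   record; names are the first whitespace-delimited token of each header.
#'   Only A/C/G/T/N are accepted.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">c1 demo", "acgt"), fa)
#' readGenomeFasta(fa)
#' @export
readGenomeFasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop("FASTA file contains no records: ", path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop("duplicate contig ids in ", path)
  if (any(Biostrings::width(seqs) == 0L)) stop("empty sequence record in ", path)
  chars <- toupper(as.character(seqs))
  bad <- grepl("[^ACGTN]", chars)
  if (any(bad)) {
    rec <- names(seqs)[which(bad)[1]]
    offending <- sort(unique(strsplit(
      gsub("[ACGTN]", "", chars[which(bad)[1]]), "")[[1]]))
    stop(sprintf("non-ACGTN character(s) [%s] in record '%s'",
      paste(offending, collapse = ","), rec))
  }
  out <- Biostrings::DNAStringSet(chars)
  names(out) <- names(seqs)
  out
}

#' Write a genome FASTA
#' @param genome named [Biostrings::DNAStringSet].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGenomeFasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 70L)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Keeps records of one feature type, optionally filtered on an attribute
#' (e.g. `biotype = "protein_coding"`); the gene id is taken from the `ID`
#' attribute. Coordinates stay 1-based inclusive.
#'
#' @param path GFF3 file.
#' @param feature GFF3 type to keep (default `"gene"`).
#' @param filter optional single named character, e.g.
#'   `c(biotype = "protein_coding")`.
#' @return a gene `GRanges` (see [geneModels()]); the `tss`/`utr5_len`
#'   columns are populated when the GFF carries same-named attributes.
#' @export
readGff3Genes <- function(path, feature = "gene", filter = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  gff <- rtracklayer::import(path, format = "gff3")
  gff <- gff[as.character(gff$type) == feature]
  if (!is.null(filter)) {
    key <- names(filter)
    if (is.null(key) || key == "") stop("'filter' must be a named value")
    vals <- if (key %in% colnames(S4Vectors::mcols(gff)))
      as.character(S4Vectors::mcols(gff)[[key]]) else rep(NA_character_, length(gff))
    gff <- gff[!is.na(vals) & vals == unname(filter)]
  }
  if (length(gff) == 0L)
    return(geneModels(character(), character(), integer(), integer(), character()))
  ids <- as.character(gff$ID)
  if (any(is.na(ids) | ids == ""))
    stop("GFF3 record(s) of type '", feature, "' without an ID attribute in ",
      path)
  if (anyDuplicated(ids))
    stop("duplicate gene ID(s) in ", path, ": ",
      paste(unique(ids[duplicated(ids)]), collapse = ", "))
  mc <- S4Vectors::mcols(gff)
  getAttr <- function(nm) if (nm %in% colnames(mc)) mc[[nm]] else NA
  geneModels(
    gene_id = ids,
    contig = as.character(GenomicRanges::seqnames(gff)),
    start = GenomicRanges::start(gff), end = GenomicRanges::end(gff),
    strand = as.character(GenomicRanges::strand(gff)),
    tss = suppressWarnings(as.integer(getAttr("tss"))),
    utr5_len = suppressWarnings(as.integer(getAttr("utr5_len"))),
    arcog = as.character(getAttr("arcog"))
  )
}

#' Write gene models to GFF3
#' @param genes gene `GRanges`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGff3Genes <- function(genes, path) {
  out <- genes
  S4Vectors::mcols(out)$type <- "gene"
  S4Vectors::mcols(out)$ID <- genes$gene_id
  keep <- !vapply(
    c("tss", "utr5_len", "arcog"),
    function(nm) all(is.na(S4Vectors::mcols(out)[[nm]])), logical(1)
  )
  for (nm in names(keep)[!keep]) S4Vectors::mcols(out)[[nm]] <- NULL
  rtracklayer::export(out, path, format = "gff3")
  invisible(path)
}

#' Read a strand-specific bedGraph end-count track
#'
#' bedGraph intervals are 0-based half-open; they are expanded to
#' per-position counts in the internal 1-based convention (bedGraph
#' position p contributes to internal position p + 1).
#'
#' @param path bedGraph file for one strand of one replicate.
#' @param contigLengths named contig lengths (nt).
#' @param strand `"+"` or `"-"`.
#' @param libraryTotal total end count of the replicate across both strand
#'   files; when `NULL`, the sum of this track alone is used (correct only
#'   for a one-track library).
#' @return an [EndTrack-class] on the raw scale.
#' @examples
#' bg <- tempfile(fileext = ".bedgraph")
#' writeLines("c1\t9\t10\t5", bg)
#' tr <- readEndTrack(bg, c(c1 = 100L), "+")
#' trackPositions(tr) # 10
#' @export
readEndTrack <- function(path, contigLengths, strand, libraryTotal = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  bg <- utils::read.table(path, sep = "\t", header = FALSE,
    col.names = c("contig", "start", "end", "value"),
    colClasses = c("character", "integer", "integer", "numeric"),
    comment.char = "#")
  if (nrow(bg) == 0L) stop("empty bedGraph: ", path)
  contig <- unique(bg$contig)
  if (length(contig) != 1L)
    stop("expected a single contig per track, found: ",
      paste(contig, collapse = ", "))
  if (!contig %in% names(contigLengths))
    stop("contig '", contig, "' not in contigLengths")
  if (any(bg$value < 0)) stop("negative value in bedGraph ", path)
  if (any(bg$end > contigLengths[[contig]]))
    stop(sprintf("interval end %d beyond contig length %d in %s",
      max(bg$end), contigLengths[[contig]], path))
  if (any(bg$start >= bg$end)) stop("malformed interval (start >= end) in ", path)
  ## expand 0-based half-open [start, end) to 1-based positions start+1 .. end
  w <- bg$end - bg$start
  pos <- sequence(w, from = bg$start + 1L)
  count <- rep(bg$value, w)
  agg <- rowsum(count, pos)
  pos <- as.integer(rownames(agg))
  count <- as.numeric(agg)
  total <- if (is.null(libraryTotal)) sum(count) else libraryTotal
  endTrack(contig, strand, pos, count, contigLengths[[contig]],
    libraryTotal = total)
}

#' Write an EndTrack as bedGraph
#'
#' Adjacent positions with identical values are collapsed into one 0-based
#' half-open interval; zero-count positions are omitted.
#'
#' @param track an [EndTrack-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeEndTrack <- function(track, path) {
  pos <- track@pos
  val <- track@count
  if (length(pos)) {
    newRun <- c(TRUE, diff(pos) != 1L | val[-1] != val[-length(val)])
    run <- cumsum(newRun)
    start0 <- pos[newRun] - 1L
    end0 <- pos[rev(!duplicated(rev(run)))]
    lines <- sprintf("%s\t%d\t%d\t%s", track@contig, start0, end0,
      formatC(val[newRun], format = "g", digits = 15))
  } else lines <- character()
  writeLines(lines, path)
  invisible(path)
}

#' Read/write a TSS table
#'
#' Tab-separated with header columns `gene`, `tss`, `utr5_len`.
#'
#' @param path TSV file.
#' @return a data.frame.
#' @export
readTssTable <- function(path) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "tss", "utr5_len")
  if (!all(need %in% colnames(tb)))
    stop("TSS table must have columns ", paste(need, collapse = ", "))
  tb
}

#' Attach TSS / 5'-UTR information to gene models
#' @param genes gene `GRanges`.
#' @param tssTable data.frame from [readTssTable()].
#' @return the annotated `GRanges`.
#' @export
addTssInfo <- function(genes, tssTable) {
  i <- match(genes$gene_id, tssTable$gene)
  genes$tss <- as.integer(tssTable$tss[i])
  genes$utr5_len <- as.integer(tssTable$utr5_len[i])
  genes
}
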