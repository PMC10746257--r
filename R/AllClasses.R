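#' @import methods
#' @importFrom S4Vectors metadata metadata<- DataFrame mcols mcols<-
NULL

setClassUnion("integerOrNULL", c("integer", "NULL"))

#' EndTrack: strand-specific per-position 3'-end counts for one replicate
#'
#' A sparse representation of the number of read 3' ends observed at each
#' genomic position on one strand of one contig, for a single sequencing
#' replicate. Tracks start out `raw` (read counts) and become `cpm` after
#' [cpmNormalize()]; the CPM scale uses the total end count of the whole
#' replicate library (both strands), so the CPM values of the paired
#' plus/minus tracks of a replicate sum to one million.
#'
#' @slot contig single contig identifier.
#' @slot strand `"+"` or `"-"`.
#' @slot pos integer vector of 1-based positions with nonzero counts.
#' @slot count numeric vector of counts (raw) or CPM values, parallel to
#'   `pos`.
#' @slot contigLength length of the contig in nt.
#' @slot libraryTotal total raw end count of the replicate across both
#'   strands; fixed at construction and preserved by normalization.
#' @slot normalized `"raw"` or `"cpm"`.
#'
#' @seealso [endTrack()], [cpmNormalize()], [readEndTrack()]
#' @export
setClass("EndTrack",
  representation(
    contig = "character",
    strand = "character",
    pos = "integer",
    count = "numeric",
    contigLength = "integer",
    libraryTotal = "numeric",
    normalized = "character"
  )
)

setValidity("EndTrack", function(object) {
  msg <- character()
  if (length(object@contig) != 1L) msg <- c(msg, "'contig' must be a single id")
  if (!object@strand %in% c("+", "-")) msg <- c(msg, "'strand' must be '+' or '-'")
  if (length(object@pos) != length(object@count))
    msg <- c(msg, "'pos' and 'count' must be parallel")
  if (any(object@count < 0)) msg <- c(msg, "counts must be non-negative")
  if (anyDuplicated(object@pos)) msg <- c(msg, "positions must be unique")
  if (length(object@pos) && (min(object@pos) < 1L ||
      max(object@pos) > object@contigLength))
    msg <- c(msg, "positions must lie within [1, contigLength]")
  if (object@libraryTotal <= 0) msg <- c(msg, "'libraryTotal' must be positive")
  if (!object@normalized %in% c("raw", "cpm"))
    msg <- c(msg, "'normalized' must be 'raw' or 'cpm'")
  if (length(msg)) msg else TRUE
})

#' Construct an EndTrack
#'
#' @param contig contig identifier.
#' @param strand `"+"` or `"-"`.
#' @param pos integer vector of 1-based positions.
#' @param count numeric vector of per-position end counts.
#' @param contigLength contig length in nt.
#' @param libraryTotal total raw end count of the replicate library (both
#'   strands); defaults to `sum(count)` which is only correct for a
#'   single-track library.
#' @param normalized `"raw"` (default) or `"cpm"`.
#' @return an [EndTrack-class] object with positions sorted.
#' @examples
#' endTrack("c1", "+", pos = c(10L, 12L), count = c(5, 2), contigLength = 100L)
#' @export
endTrack <- function(contig, strand, pos, count, contigLength,
                     libraryTotal = sum(count), normalized = "raw") {
  keep <- count != 0
  pos <- as.integer(pos)[keep]
  count <- as.numeric(count)[keep]
  o <- order(pos)
  new("EndTrack",
    contig = as.character(contig), strand = strand,
    pos = pos[o], count = count[o],
    contigLength = as.integer(contigLength),
    libraryTotal = as.numeric(libraryTotal),
    normalized = normalized
  )
}

setMethod("show", "EndTrack", function(object) {
  cat(sprintf(
    "EndTrack %s(%s): %d nonzero positions, %s scale, library total %.4g\n",
    object@contig, object@strand, length(object@pos),
    object@normalized, object@libraryTotal
  ))
})

#' @describeIn EndTrack-class number of nonzero positions
#' @param x,object an `EndTrack`
#' @export
setMethod("length", "EndTrack", function(x) length(x@pos))

#' Accessors for EndTrack slots
#'
#' @param x an [EndTrack-class].
#' @return `trackPositions()` the integer positions; `trackCounts()` the
#'   parallel counts; `trackStrand()`, `trackContig()` the strand/contig;
#'   `libraryTotal()` the library total; `isNormalized()` whether the track
#'   is on the CPM scale.
#' @name EndTrack-accessors
NULL

#' @rdname EndTrack-accessors
#' @export
trackPositions <- function(x) x@pos
#' @rdname EndTrack-accessors
#' @export
trackCounts <- function(x) x@count
#' @rdname EndTrack-accessors
#' @export
trackStrand <- function(x) x@strand
#' @rdname EndTrack-accessors
#' @export
trackContig <- function(x) x@contig
#' @rdname EndTrack-accessors
#' @export
libraryTotal <- function(x) x@libraryTotal
#' @rdname EndTrack-accessors
#' @export
isNormalized <- function(x) x@normalized == "cpm"

#' MotifPWM: position weight matrix with background model
#'
#' A nucleotide position weight matrix storing per-position base
#' probabilities and the corresponding log2-odds scores against a background
#' base distribution. Built from a degenerate IUPAC consensus with
#' [pwmFromConsensus()] and scanned with [pwmScanPvalue()], which computes
#' exact score-distribution p-values by dynamic programming.
#'
#' @slot probs 4 x L matrix of base probabilities (rows A, C, G, T).
#' @slot scores 4 x L matrix of log2-odds scores against `background`.
#' @slot background length-4 base probabilities (A, C, G, T), summing to 1.
#' @slot pseudocount pseudo-probability added before taking log-odds.
#' @export
setClass("MotifPWM",
  representation(
    probs = "matrix",
    scores = "matrix",
    background = "numeric",
    pseudocount = "numeric"
  )
)

setValidity("MotifPWM", function(object) {
  msg <- character()
  if (nrow(object@probs) != 4L || nrow(object@scores) != 4L)
    msg <- c(msg, "probability and score matrices must have 4 rows (A,C,G,T)")
  if (!all(dim(object@probs) == dim(object@scores)))
    msg <- c(msg, "probs and scores must have identical dimensions")
  if (length(object@background) != 4L || any(object@background <= 0))
    msg <- c(msg, "background must be 4 strictly positive probabilities")
  if (abs(sum(object@background) - 1) > 1e-8)
    msg <- c(msg, "background must sum to 1")
  if (any(!is.finite(object@scores))) msg <- c(msg, "scores must be finite")
  if (length(msg)) msg else TRUE
})

setMethod("show", "MotifPWM", function(object) {
  cat(sprintf(
    "MotifPWM of length %d (max score %.3f, background %s)\n",
    ncol(object@scores), sum(apply(object@scores, 2, max)),
    paste(sprintf("%.2f", object@background), collapse = "/")
  ))
})

#' @describeIn MotifPWM-class motif length in nt
#' @param x,object a `MotifPWM`
#' @export
setMethod("length", "MotifPWM", function(x) ncol(x@scores))

#' @rdname MotifPWM-class
#' @export
pwmScores <- function(x) x@scores
#' @rdname MotifPWM-class
#' @export
pwmBackground <- function(x) x@background

#' SimConfig: parameters of the synthetic thermal-stress study generator
#'
#' Bundles every tunable of the synthetic-data generator: genome/annotation
#' layout, planted promoter/terminator fractions, the Term-seq noise model,
#' the RNA/protein abundance model with planted differential expression and
#' profile clusters, and the experimental design (conditions x replicates).
#' Defaults emulate a four-replicate design with seven stress conditions
#' plus a control, as in temperature-stress time courses of
#' hyperthermophilic archaea.
#'
#' @slot seed integer RNG seed; the whole simulation is deterministic in it.
#' @slot nGenes number of genes to place.
#' @slot contigLength genome length in nt (single contig).
#' @slot gc genomic GC fraction.
#' @slot leaderlessFraction probability that a gene has a 0-nt 5' UTR.
#' @slot promoterFraction fraction of genes given a planted BRE/TATA
#'   promoter instance at -38..-26 relative to the TSS.
#' @slot polyUFraction fraction of genes given a planted U-rich terminator
#'   immediately upstream of the true primary 3' end.
#' @slot secondaryFraction fraction of genes with an additional (secondary)
#'   downstream 3' end.
#' @slot internalFraction fraction of genes with an internal 3' end.
#' @slot regulonFraction fraction of genes given a planted palindromic
#'   regulator binding site upstream of the TSS.
#' @slot nReplicates replicates per condition (>= 3).
#' @slot conditions ordered condition labels; must contain `"Ctrl"`.
#' @slot pi0 probability that a gene's log2 fold change is exactly 0 in a
#'   given condition (genes not assigned to a profile cluster).
#' @slot deMu,deSigma mean/sd of the normal draw for nonzero planted log2
#'   fold changes.
#' @slot rnaProteinRho target correlation between planted RNA and protein
#'   effects.
#' @slot kTrue number of planted profile clusters (0 disables).
#' @slot clusterFraction fraction of genes assigned to profile clusters.
#' @slot clusterAmplitude log2FC amplitude of the cluster templates.
#' @slot clusterSigma within-cluster per-condition sd of gene effects.
#' @slot dispersion NB dispersion of RNA counts (and Term-seq end counts).
#' @slot proteinSigma lognormal sd (log2 scale) of protein intensities.
#' @slot baselineMeanLog,baselineSdLog log-scale location/spread of RNA
#'   baseline means.
#' @slot endHeightMeanLog,endHeightSdLog,endHeightMin lognormal location,
#'   spread and floor of planted primary 3'-end heights (expected counts).
#' @slot jitterSd sd (nt) of the per-read Gaussian positional jitter of
#'   Term-seq reads (rounded to integers).
#' @slot backgroundRate background end-read rate per nt per replicate.
#' @slot nCategories number of functional categories; labels `C01`, ...
#' @slot enrichedCategory index of the category overrepresented among
#'   cluster (differentially expressed) genes; 0 disables.
#' @slot enrichmentFold overrepresentation factor of the enriched category.
#' @slot lengthBiasStrength strength of the gene-length bias on DE
#'   assignment probability (0 = none).
#' @seealso [simConfig()], [makeGenomeAnnotation()], [simulateTermseq()],
#'   [simulateOmics()], [simulateLongreads()]
#' @export
setClass("SimConfig",
  representation(
    seed = "integer", nGenes = "integer", contigLength = "integer",
    gc = "numeric", leaderlessFraction = "numeric",
    promoterFraction = "numeric", polyUFraction = "numeric",
    secondaryFraction = "numeric", internalFraction = "numeric",
    regulonFraction = "numeric",
    nReplicates = "integer", conditions = "character",
    pi0 = "numeric", deMu = "numeric", deSigma = "numeric",
    rnaProteinRho = "numeric",
    kTrue = "integer", clusterFraction = "numeric",
    clusterAmplitude = "numeric", clusterSigma = "numeric",
    dispersion = "numeric", proteinSigma = "numeric",
    baselineMeanLog = "numeric", baselineSdLog = "numeric",
    endHeightMeanLog = "numeric", endHeightSdLog = "numeric",
    endHeightMin = "numeric",
    jitterSd = "numeric", backgroundRate = "numeric",
    nCategories = "integer", enrichedCategory = "integer",
    enrichmentFold = "numeric", lengthBiasStrength = "numeric"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  fr <- c(
    gc = object@gc, leaderless = object@leaderlessFraction,
    promoter = object@promoterFraction, polyU = object@polyUFraction,
    secondary = object@secondaryFraction, internal = object@internalFraction,
    regulon = object@regulonFraction, pi0 = object@pi0,
    cluster = object@clusterFraction
  )
  if (any(fr < 0 | fr > 1)) msg <- c(msg, "all fractions must lie in [0, 1]")
  if (object@gc <= 0 || object@gc >= 1) msg <- c(msg, "gc must be in (0, 1)")
  if (object@nReplicates < 3L) msg <- c(msg, "nReplicates must be >= 3")
  if (!"Ctrl" %in% object@conditions)
    msg <- c(msg, "conditions must contain 'Ctrl'")
  if (object@nGenes < 1L) msg <- c(msg, "nGenes must be positive")
  if (abs(object@rnaProteinRho) > 1) msg <- c(msg, "rnaProteinRho in [-1, 1]")
  if (object@dispersion <= 0) msg <- c(msg, "dispersion must be positive")
  if (length(msg)) msg else TRUE
})

#' Create a synthetic-study configuration
#'
#' All arguments default to the standard study conditions (see
#' [SimConfig-class] for meanings); override any subset by name.
#'
#' @param seed integer seed.
#' @param ... named overrides of [SimConfig-class] slots.
#' @return a validated [SimConfig-class].
#' @examples
#' cfg <- simConfig(seed = 1, nGenes = 50)
#' @export
simConfig <- function(seed = 1L, ...) {
  defaults <- list(
    seed = as.integer(seed), nGenes = 200L, contigLength = 400000L,
    gc = 0.41, leaderlessFraction = 0.25,
    promoterFraction = 0.6, polyUFraction = 0.6,
    secondaryFraction = 0.25, internalFraction = 0.15,
    regulonFraction = 0.05,
    nReplicates = 4L,
    conditions = c("Ctrl", "CS1", "CS2", "CS3", "CSR", "HS1", "HS2", "HSR"),
    pi0 = 0.7, deMu = 0, deSigma = 1.5,
    rnaProteinRho = 0.7,
    kTrue = 4L, clusterFraction = 0.3,
    clusterAmplitude = 2, clusterSigma = 0.4,
    dispersion = 0.05, proteinSigma = 0.35,
    baselineMeanLog = log(200), baselineSdLog = 1,
    endHeightMeanLog = log(500), endHeightSdLog = 0.8, endHeightMin = 20,
    jitterSd = 1, backgroundRate = 5e-4,
    nCategories = 20L, enrichedCategory = 1L,
    enrichmentFold = 3, lengthBiasStrength = 0
  )
  override <- list(...)
  bad <- setdiff(names(override), names(defaults))
  if (length(bad)) stop("unknown SimConfig fields: ", paste(bad, collapse = ", "))
  defaults[names(override)] <- override
  intSlots <- c(
    "seed", "nGenes", "contigLength", "nReplicates", "kTrue",
    "nCategories", "enrichedCategory"
  )
  for (s in intSlots) defaults[[s]] <- as.integer(defaults[[s]])
  do.call(new, c(list("SimConfig"), defaults))
}

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    "SimConfig: %d genes on %d nt, %d conditions x %d replicates, seed %d\n",
    object@nGenes, object@contigLength, length(object@conditions),
    object@nReplicates, object@seed
  ))
})

#' OmicsExperiment: genes x samples abundance assay with stress design
#'
#' A thin extension of
#' [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' carrying one assay (`counts` for RNA, `intensity` for protein), a
#' `condition`/`replicate` design in `colData`, and for RNA a `length`
#' column (nt) in `rowData` used by [tpmNormalize()].
#'
#' @slot kind `"rna"` or `"protein"`.
#' @seealso [omicsExperiment()], [rnaDeTest()], [proteinDeTest()]
#' @export
#' @import SummarizedExperiment
setClass("OmicsExperiment",
  contains = "SummarizedExperiment",
  representation(kind = "character")
)

setValidity("OmicsExperiment", function(object) {
  msg <- character()
  if (!object@kind %in% c("rna", "protein"))
    msg <- c(msg, "'kind' must be 'rna' or 'protein'")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("condition", "replicate") %in% colnames(cd)))
    msg <- c(msg, "colData must contain 'condition' and 'replicate'")
  else if (!"Ctrl" %in% cd$condition)
    msg <- c(msg, "design must include a 'Ctrl' condition")
  a <- SummarizedExperiment::assay(object)
  if (any(a[!is.na(a)] < 0)) msg <- c(msg, "abundances must be non-negative")
  if (object@kind == "rna") {
    rd <- SummarizedExperiment::rowData(object)
    if (!"length" %in% colnames(rd))
      msg <- c(msg, "RNA experiments need a rowData 'length' column")
    else if (any(rd$length <= 0)) msg <- c(msg, "gene lengths must be positive")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an OmicsExperiment
#'
#' @param values genes x samples matrix (RNA counts or protein intensities;
#'   `NA` allowed for protein).
#' @param condition,replicate per-sample design vectors.
#' @param kind `"rna"` or `"protein"`.
#' @param lengths per-gene lengths in nt (required for RNA).
#' @return an [OmicsExperiment-class].
#' @examples
#' m <- matrix(rpois(8, 50), 2, dimnames = list(c("g1", "g2"), NULL))
#' omicsExperiment(m, rep(c("Ctrl", "HS1"), each = 2), rep(1:2, 2),
#'   kind = "rna", lengths = c(900, 1500))
#' @export
omicsExperiment <- function(values, condition, replicate, kind = c("rna", "protein"),
                            lengths = NULL) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (is.null(colnames(values)))
    colnames(values) <- paste(condition, replicate, sep = "_")
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("gene%05d", seq_len(nrow(values)))
  cd <- S4Vectors::DataFrame(
    condition = as.character(condition),
    replicate = as.integer(replicate), row.names = colnames(values)
  )
  rd <- S4Vectors::DataFrame(row.names = rownames(values))
  if (!is.null(lengths)) rd$length <- as.numeric(lengths)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = stats::setNames(list(values), if (kind == "rna") "counts" else "intensity"),
    colData = cd, rowData = rd
  )
  new("OmicsExperiment", se, kind = kind)
}

#' @rdname OmicsExperiment-class
#' @param x an `OmicsExperiment`
#' @export
omicsKind <- function(x) x@kind

#' @rdname OmicsExperiment-class
#' @export
omicsConditions <- function(x) SummarizedExperiment::colData(x)$condition

#' @rdname OmicsExperiment-class
#' @export
geneLengths <- function(x) SummarizedExperiment::rowData(x)$length

setMethod("show", "OmicsExperiment", function(object) {
  cat(sprintf(
    "OmicsExperiment (%s): %d genes x %d samples, %d conditions\n",
    object@kind, nrow(object), ncol(object),
    length(unique(omicsConditions(object)))
  ))
})
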