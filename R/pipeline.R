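## End-to-end orchestration of the synthetic-study pipeline with a single
## configuration, fixed seeds and a reproducibility manifest.

#' Default pipeline configuration
#'
#' @param seed master seed (propagated to the simulation and every
#'   stochastic stage).
#' @param outdir output directory.
#' @param ... named overrides for the `simulate` stage (see
#'   [simConfig()]).
#' @return nested configuration list with per-stage parameter blocks
#'   (`simulate`, `ends`, `regseq`, `de`, `enrich`, `cluster`).
#' @export
pipelineConfig <- function(seed = 7L, outdir = tempfile("termomics_run_"),
                           ...) {
  list(
    seed = as.integer(seed),
    outdir = outdir,
    simulate = list(seed = as.integer(seed), ...),
    ends = list(minReplicates = 3L, minCpm = 5, mergeWindow = 3L,
      downstreamWindow = 300L),
    regseq = list(alpha = 1e-3, nBackground = 100000L,
      uWindow = 8L, minU = 6L),
    de = list(ctrl = "Ctrl"),
    enrich = list(alpha = 0.05, contrast = NULL),
    cluster = list(kRange = 2:8, maxMissing = 0.5)
  )
}

#' Run the full pipeline on a configuration
#'
#' Executes simulate, ends, regseq, de, enrich and cluster in dependency
#' order, writing each stage's outputs under `cfg$outdir` and recording a
#' manifest (stage parameters, output files, md5 checksums). Identical
#' configurations and seeds give identical checksums. When a
#' configuration names input files instead of a simulation, their
#' existence is validated before any stage runs.
#'
#' @param cfg configuration list from [pipelineConfig()], or the path of
#'   a YAML file with the same structure.
#' @return the manifest (list), invisibly; also written as
#'   `run_manifest.json` in `outdir`.
#' @export
runPipeline <- function(cfg = pipelineConfig()) {
  if (is.character(cfg)) cfg <- yaml::read_yaml(cfg)
  for (f in unlist(cfg$input)) {
    if (!file.exists(f)) stop("input file does not exist: ", f)
  }
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "termOmics",
    version = as.character(utils::packageVersion("termOmics")),
    seed = cfg$seed, stages = list())
  note <- function(stage, params, files) {
    manifest$stages[[stage]] <<- list(
      parameters = params,
      outputs = as.list(files),
      md5 = as.list(tools::md5sum(unlist(files)))
    )
    message("stage ", stage, ": ", length(files), " output file(s)")
  }

  ## --- simulate -------------------------------------------------------
  scfg <- do.call(simConfig, cfg$simulate)
  sim <- makeGenomeAnnotation(scfg)
  tracks <- simulateTermseq(scfg, sim$truth)
  omics <- simulateOmics(scfg, sim$truth)
  files <- writeSimulation(sim, tracks, omics, file.path(cfg$outdir, "sim"))
  note("simulate", cfg$simulate, files)

  ## --- ends -----------------------------------------------------------
  ep <- cfg$ends
  cpm <- lapply(tracks, function(tr)
    list(plus = cpmNormalize(tr$plus), minus = cpmNormalize(tr$minus)))
  ends <- rbind(
    callConsensusEnds(lapply(cpm, `[[`, "plus"), ep$minReplicates,
      ep$minCpm, ep$mergeWindow),
    callConsensusEnds(lapply(cpm, `[[`, "minus"), ep$minReplicates,
      ep$minCpm, ep$mergeWindow)
  )
  calls <- classifyEnds(ends, sim$genes, ep$downstreamWindow)
  utr3 <- utr3Lengths(calls, sim$genes)
  endsTsv <- file.path(cfg$outdir, "end_calls.tsv")
  utils::write.table(calls, endsTsv, sep = "\t", quote = FALSE,
    row.names = FALSE)
  bed <- file.path(cfg$outdir, "end_calls.bed")
  writeLines(sprintf("%s\t%d\t%d\t%s\t%.3f\t%s", calls$contig,
    calls$position - 1L, calls$position,
    paste0(ifelse(is.na(calls$gene_id), ".", calls$gene_id), ":",
      calls$end_class),
    calls$height, calls$strand), bed)
  utr3Tsv <- file.path(cfg$outdir, "utr3_lengths.tsv")
  utils::write.table(utr3, utr3Tsv, sep = "\t", quote = FALSE,
    row.names = FALSE)
  note("ends", ep, c(ends = endsTsv, bed = bed, utr3 = utr3Tsv))

  ## --- regseq ---------------------------------------------------------
  rp <- cfg$regseq
  prom <- classifyPromoters(sim$genes, sim$genome, alpha = rp$alpha)
  primary <- calls[calls$end_class == "primary", , drop = FALSE]
  pu <- classifyPolyU(primary, sim$genome, uWindow = rp$uWindow,
    minU = rp$minU)
  ig <- intergenicIntervals(sim$genes,
    stats::setNames(Biostrings::width(sim$genome), names(sim$genome)))
  termSeqs <- vapply(seq_len(nrow(pu)), function(i)
    senseWindow(sim$genome, pu$contig[i], pu$position[i], pu$strand[i],
      -35L, 2L), character(1))
  enr <- nucleotideEnrichment(termSeqs[!is.na(termSeqs)], sim$genome, ig,
    nBackground = rp$nBackground, seed = cfg$seed)
  tpm <- tpmNormalize(omics$rna)
  ctrlTpm <- rowMeans(tpm[, omicsConditions(omics$rna) == "Ctrl", drop = FALSE])
  refSet <- names(sort(ctrlTpm, decreasing = TRUE))[
    seq_len(max(1L, ceiling(0.05 * length(ctrlTpm))))]
  comp <- sequenceComposition(sim$genes, sim$genome, refSet)
  regseqTsv <- file.path(cfg$outdir, "gene_features.tsv")
  feat <- merge(prom, comp, by = "gene_id", all = TRUE)
  feat <- merge(feat, pu[, c("gene_id", "polyU", "max_u")], by = "gene_id",
    all.x = TRUE)
  utils::write.table(feat, regseqTsv, sep = "\t", quote = FALSE,
    row.names = FALSE)
  enrTsv <- file.path(cfg$outdir, "terminator_enrichment.tsv")
  utils::write.table(
    data.frame(base = rownames(enr), enr, check.names = FALSE), enrTsv,
    sep = "\t", quote = FALSE, row.names = FALSE)
  note("regseq", rp, c(features = regseqTsv, enrichment = enrTsv))

  ## --- de -------------------------------------------------------------
  deRna <- deAnalysis(omics$rna, ctrl = cfg$de$ctrl)
  deProt <- deAnalysis(omics$protein, ctrl = cfg$de$ctrl)
  deTsv <- file.path(cfg$outdir, "de_records.tsv")
  utils::write.table(rbind(cbind(layer = "rna", deRna),
    cbind(layer = "protein", deProt)), deTsv, sep = "\t",
    quote = FALSE, row.names = FALSE)
  note("de", cfg$de, c(de = deTsv))

  ## --- enrich ---------------------------------------------------------
  contrast <- cfg$enrich$contrast
  if (is.null(contrast))
    contrast <- setdiff(unique(omicsConditions(omics$rna)), cfg$de$ctrl)[1]
  sub <- deRna[deRna$contrast == paste0(contrast, "_vs_", cfg$de$ctrl), ]
  gi <- match(sub$gene_id, sim$genes$gene_id)
  enrich <- do.call(rbind, lapply(c("up", "down"), function(dir) {
    tryCatch(
      arcogEnrichment(sub$group, sim$genes$arcog[gi],
        GenomicRanges::width(sim$genes)[gi], direction = dir,
        alpha = cfg$enrich$alpha),
      error = function(e) NULL
    )
  }))
  enrichTsv <- file.path(cfg$outdir, "category_enrichment.tsv")
  utils::write.table(enrich, enrichTsv, sep = "\t", quote = FALSE,
    row.names = FALSE)
  note("enrich", cfg$enrich, c(enrichment = enrichTsv))

  ## --- cluster --------------------------------------------------------
  mkFc <- function(de) {
    conds <- unique(de$contrast)
    m <- sapply(conds, function(cc) {
      s <- de[de$contrast == cc, ]
      s$log2FC[match(unique(de$gene_id), s$gene_id)]
    })
    rownames(m) <- unique(de$gene_id)
    colnames(m) <- sub("_vs_.*$", "", conds)
    m
  }
  fc <- list(rna = mkFc(deRna))
  fcP <- mkFc(deProt)
  common <- intersect(rownames(fc$rna), rownames(fcP))
  fc <- list(rna = fc$rna[common, , drop = FALSE],
    protein = fcP[common, , drop = FALSE])
  zs <- zscoreRows(fc)
  cl <- clusterGenes(zs$z, kRange = cfg$cluster$kRange,
    maxMissing = cfg$cluster$maxMissing)
  prof <- clusterProfiles(cl$assignment, zs$z)
  clusterTsv <- file.path(cfg$outdir, "cluster_assignment.tsv")
  utils::write.table(
    data.frame(gene_id = names(cl$assignment), cluster = cl$assignment),
    clusterTsv, sep = "\t", quote = FALSE, row.names = FALSE)
  elbowTsv <- file.path(cfg$outdir, "elbow_curve.tsv")
  utils::write.table(cl$elbow, elbowTsv, sep = "\t", quote = FALSE,
    row.names = FALSE)
  profTsv <- file.path(cfg$outdir, "cluster_profiles.tsv")
  utils::write.table(prof, profTsv, sep = "\t", quote = FALSE,
    row.names = FALSE)
  note("cluster", cfg$cluster,
    c(assignment = clusterTsv, elbow = elbowTsv, profiles = profTsv))

  manifestPath <- file.path(cfg$outdir, "run_manifest.json")
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
    pretty = TRUE)
  invisible(manifest)
}
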