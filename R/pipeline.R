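# Pipeline configuration and the subcommand driver tying the stages
# together. All defaults are the standard workflow parameters (intensity
# threshold 1e5, S/N 5, min height 1e5, RT tolerance 0.05 min, alignment /
# annotation / network cosine thresholds 0.7, TopK 10, 999 permutations,
# EGA 100 -> 900 degC at 10 degC/min with a 1 min hold, 650 degC
# inorganic-carbon cutoff).

#' Pipeline configuration
#'
#' @param intensityThreshold EIC existence threshold, counts (default 1e5).
#' @param minSN minimum peak signal-to-noise (default 5).
#' @param minHeight minimum feature height, counts (default 1e5).
#' @param rtTol retention-time tolerance, minutes (default 0.05).
#' @param alignThreshold alignment score threshold (default 0.7).
#' @param wRt RT weight in the alignment score (default 0.5).
#' @param annotateMinCosine library-annotation cosine threshold (default 0.7).
#' @param networkMinCosine network edge cosine threshold (default 0.7).
#' @param topK maximum neighbors per network node (default 10).
#' @param nPerm PERMANOVA permutations (default 999).
#' @param egaStartTemp,egaHold,egaRampRate,egaEndTemp EGA temperature
#'   program (defaults 100 degC, 1 min, 10 degC/min, 900 degC).
#' @param icCutoff high-temperature flag cutoff, degC (default 650).
#' @param seed integer seed for every stochastic stage (default 1).
#' @return Named list of validated parameters.
#' @export
pipelineConfig <- function(intensityThreshold = 1e5, minSN = 5,
                           minHeight = 1e5, rtTol = 0.05,
                           alignThreshold = 0.7, wRt = 0.5,
                           annotateMinCosine = 0.7, networkMinCosine = 0.7,
                           topK = 10, nPerm = 999, egaStartTemp = 100,
                           egaHold = 1, egaRampRate = 10, egaEndTemp = 900,
                           icCutoff = 650, seed = 1) {
  cfg <- as.list(environment())
  stopifnot(intensityThreshold > 0, minSN >= 1, minHeight > 0, rtTol > 0,
            alignThreshold > 0, alignThreshold <= 1, wRt >= 0, wRt <= 1,
            annotateMinCosine > 0, annotateMinCosine <= 1,
            networkMinCosine > 0, networkMinCosine <= 1, topK >= 1,
            nPerm >= 1, egaEndTemp > egaStartTemp, egaRampRate > 0,
            egaHold >= 0)
  cfg
}

#' Read a flat key = value configuration file
#'
#' Unknown keys are an error; values are coerced to the type of the
#' corresponding [pipelineConfig()] default.
#'
#' @param path configuration file; lines `key = value`, `#` comments.
#' @return A validated configuration list.
#' @export
readPipelineConfig <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- lines[grepl("=", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, function(x) trimws(x[1]), character(1))
  vals <- vapply(kv, function(x) trimws(paste(x[-1], collapse = "=")),
                 character(1))
  known <- names(formals(pipelineConfig))
  bad <- setdiff(keys, known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  args <- stats::setNames(lapply(vals, function(v) as.numeric(v)), keys)
  do.call(pipelineConfig, args)
}

#' Run one pipeline stage
#'
#' File-level driver over the package functions. Identical configuration and
#' inputs give identical outputs; every stage writes a machine-readable run
#' log (`<cmd>_log.json`: parameters, package version, seed, md5 digests of
#' the inputs) next to its outputs.
#'
#' Subcommands and their artifacts:
#' \describe{
#'   \item{simulate}{writes `sample_<i>.mzML`, `library.msp`, `classes.csv`,
#'     `truth.csv` (options via `...`: `nCompounds`, `nSamples`,
#'     `coElutePairs`, `noiseSd`).}
#'   \item{deconvolve}{`inputs$mzml` (paths) -> `<sample>_features.csv` +
#'     `<sample>_features.msp`.}
#'   \item{align}{`inputs$features` (csv paths; sibling `.msp` assumed) ->
#'     `aligned_quant.csv`, `consensus.mgf`.}
#'   \item{annotate}{`inputs$mgf`, `inputs$library` -> `annotations.csv`.}
#'   \item{classify}{`inputs$annotations`, `inputs$classes` ->
#'     `annotations_classified.csv`.}
#'   \item{network}{`inputs$mgf`, `inputs$annotations` [, `inputs$quant`,
#'     `inputs$groups`] -> `edges.tsv`, `network.graphml`, `clusters.txt`.}
#'   \item{propagate}{`inputs$mgf`, `inputs$annotations` ->
#'     `annotations_propagated.csv`, `network_propagated.graphml`.}
#'   \item{stats}{`inputs$quant`, `inputs$annotations`, `inputs$groups` ->
#'     `class_abundance.csv`, `diversity.csv`, `bray_curtis.csv`,
#'     `permanova.json`, `dendrogram.nwk`.}
#'   \item{ega}{`inputs$mzml` (one path) -> `ega_tic.csv`, `ega_peaks.csv`,
#'     `high_temp.json`.}
#' }
#'
#' @param cmd subcommand name (see Details).
#' @param inputs named list of input paths.
#' @param outDir output directory (created if missing).
#' @param config configuration from [pipelineConfig()].
#' @param ... subcommand-specific options (see `simulate`).
#' @return Named character vector of the written artifact paths, invisibly.
#' @export
runPipeline <- function(cmd = c("simulate", "deconvolve", "align", "annotate",
                                "classify", "network", "propagate", "stats",
                                "ega"),
                        inputs = list(), outDir = ".",
                        config = pipelineConfig(), ...) {
  cmd <- match.arg(cmd)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  for (p in unlist(inputs))
    if (!file.exists(p)) stop("missing input: ", p)
  out <- switch(cmd,
    simulate = stageSimulate(outDir, config, ...),
    deconvolve = stageDeconvolve(inputs, outDir, config),
    align = stageAlign(inputs, outDir, config),
    annotate = stageAnnotate(inputs, outDir, config),
    classify = stageClassify(inputs, outDir, config),
    network = stageNetwork(inputs, outDir, config, propagate = FALSE),
    propagate = stageNetwork(inputs, outDir, config, propagate = TRUE),
    stats = stageStats(inputs, outDir, config),
    ega = stageEGA(inputs, outDir, config))
  log <- list(command = cmd, parameters = config,
              package = as.character(utils::packageVersion("pyrosom")),
              inputs = as.list(vapply(unlist(inputs), function(p)
                unname(tools::md5sum(p)), character(1))),
              artifacts = as.list(out))
  logPath <- file.path(outDir, paste0(cmd, "_log.json"))
  jsonlite::write_json(log, logPath, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(c(out, log = logPath))
}

stageSimulate <- function(outDir, config, nCompounds = 20, nSamples = 2,
                          coElutePairs = 0, noiseSd = 0) {
  cmp <- genCompoundSet(nCompounds, seed = config$seed)
  paths <- character()
  truth <- NULL
  for (s in seq_len(nSamples)) {
    g <- genRun(cmp, noiseSd = noiseSd, coElutePairs = coElutePairs,
                seed = config$seed + s)
    p <- file.path(outDir, sprintf("sample_%d.mzML", s))
    writeMzML(g$run, p)
    paths[sprintf("mzml_%d", s)] <- p
    if (is.null(truth)) truth <- g$truth
  }
  libs <- genLibrary(cmp)
  paths["library"] <- writeMSP(libs$library, file.path(outDir, "library.msp"))
  cdf <- data.frame(compound = vapply(cmp, `[[`, character(1), "name"),
                    class = vapply(cmp, `[[`, character(1), "compoundClass"))
  utils::write.csv(cdf, file.path(outDir, "classes.csv"), row.names = FALSE)
  paths["classes"] <- file.path(outDir, "classes.csv")
  utils::write.csv(truth, file.path(outDir, "truth.csv"), row.names = FALSE)
  paths["truth"] <- file.path(outDir, "truth.csv")
  paths
}

stageDeconvolve <- function(inputs, outDir, config) {
  paths <- character()
  for (p in unlist(inputs$mzml)) {
    sid <- tools::file_path_sans_ext(basename(p))
    run <- readMzML(p, mode = "pyrolysis")
    feats <- deconvolve(run, intensityThreshold = config$intensityThreshold,
                        minSN = config$minSN, minHeight = config$minHeight,
                        rtTol = config$rtTol, sampleId = sid)
    fcsv <- file.path(outDir, paste0(sid, "_features.csv"))
    featureTable(feats, fcsv)
    fmsp <- file.path(outDir, paste0(sid, "_features.msp"))
    writeMSP(lapply(seq_along(feats), function(k)
      LibraryEntry(sprintf("%s_F%d", sid, k), feats[[k]]@spectrum)), fmsp)
    paths[paste0(sid, "_csv")] <- fcsv
    paths[paste0(sid, "_msp")] <- fmsp
  }
  paths
}

readFeatureFiles <- function(csvPaths) {
  feats <- list()
  for (p in csvPaths) {
    df <- utils::read.csv(p, stringsAsFactors = FALSE)
    msp <- sub("\\.csv$", ".msp", p)
    lib <- readMSP(msp)
    for (k in seq_len(nrow(df)))
      feats[[length(feats) + 1L]] <- Feature(
        df$rt_min[k], lib[[k]]@spectrum, df$height[k], df$area[k],
        sampleId = df$sample_id[k])
  }
  feats
}

stageAlign <- function(inputs, outDir, config) {
  feats <- readFeatureFiles(unlist(inputs$features))
  aligned <- alignFeatures(feats, scoreThreshold = config$alignThreshold,
                           rtTol = config$rtTol, wRt = config$wRt)
  qcsv <- file.path(outDir, "aligned_quant.csv")
  quantificationTable(aligned, qcsv)
  mgf <- file.path(outDir, "consensus.mgf")
  writeMGF(consensusSpectra(aligned), mgf)
  c(quant = qcsv, mgf = mgf)
}

readQuantCSV <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  Q <- as.matrix(df[, -1, drop = FALSE])
  rownames(Q) <- df[[1]]
  Q
}

stageAnnotate <- function(inputs, outDir, config) {
  nodes <- readMGF(inputs$mgf)
  lib <- readMSP(inputs$library)
  ann <- annotateFeatures(lapply(nodes, function(e) e@spectrum), lib,
                          minCosine = config$annotateMinCosine)
  ann$nodeId <- names(nodes)
  p <- file.path(outDir, "annotations.csv")
  utils::write.csv(ann, p, row.names = FALSE, na = "")
  c(annotations = p)
}

stageClassify <- function(inputs, outDir, config) {
  ann <- utils::read.csv(inputs$annotations, stringsAsFactors = FALSE,
                         na.strings = c("NA", ""))
  cl <- readClassLibrary(inputs$classes)
  ann <- assignClasses(ann, cl)
  p <- file.path(outDir, "annotations_classified.csv")
  utils::write.csv(ann, p, row.names = FALSE, na = "")
  c(annotations = p)
}

stageNetwork <- function(inputs, outDir, config, propagate = FALSE) {
  nodes <- readMGF(inputs$mgf)
  ann <- utils::read.csv(inputs$annotations, stringsAsFactors = FALSE,
                         na.strings = c("NA", ""))
  abundance <- NULL
  if (!is.null(inputs$quant) && !is.null(inputs$groups)) {
    Q <- readQuantCSV(inputs$quant)
    gdf <- utils::read.csv(inputs$groups, stringsAsFactors = FALSE)
    eco <- factor(gdf$group[match(colnames(Q), gdf$sample)])
    abundance <- t(apply(Q, 1, function(r) tapply(r, eco, sum)))
    colnames(abundance) <- levels(eco)
  }
  net <- buildNetwork(lapply(nodes, function(e) e@spectrum), ann,
                      abundance = abundance,
                      minCosine = config$networkMinCosine,
                      topK = config$topK)
  if (propagate) {
    net <- propagateClasses(net)
    acsv <- file.path(outDir, "annotations_propagated.csv")
    utils::write.csv(nodeData(net), acsv, row.names = FALSE, na = "")
    gml <- file.path(outDir, "network_propagated.graphml")
    writeGraphML(net, gml)
    return(c(annotations = acsv, graphml = gml))
  }
  etsv <- file.path(outDir, "edges.tsv")
  writeEdgeList(net, etsv)
  gml <- file.path(outDir, "network.graphml")
  writeGraphML(net, gml)
  ctxt <- file.path(outDir, "clusters.txt")
  cls <- networkClusters(net)
  writeLines(vapply(cls, paste, character(1), collapse = "\t"), ctxt)
  c(edges = etsv, graphml = gml, clusters = ctxt)
}

stageStats <- function(inputs, outDir, config) {
  Q <- readQuantCSV(inputs$quant)
  ann <- utils::read.csv(inputs$annotations, stringsAsFactors = FALSE,
                         na.strings = c("NA", ""))
  gdf <- utils::read.csv(inputs$groups, stringsAsFactors = FALSE)
  groups <- gdf$group[match(colnames(Q), gdf$sample)]
  cls <- ann$compoundClass[match(rownames(Q), ann$nodeId)]
  paths <- character()

  cra <- classRelativeAbundance(Q, cls)
  p <- file.path(outDir, "class_abundance.csv")
  utils::write.csv(data.frame(sample = rownames(cra), cra,
                              check.names = FALSE), p, row.names = FALSE)
  paths["class_abundance"] <- p

  shares <- apply(Q, 2, function(col) col / sum(col))
  div <- data.frame(
    sample = colnames(Q),
    shannon = apply(shares, 2, shannonIndex),
    simpson = apply(shares, 2, simpsonIndex))
  p <- file.path(outDir, "diversity.csv")
  utils::write.csv(div, p, row.names = FALSE)
  paths["diversity"] <- p

  # replicate-averaged compound intensities for the dissimilarity analyses
  eco <- factor(groups)
  avg <- t(apply(Q, 1, function(r) tapply(r, eco, mean)))
  D <- brayCurtisMatrix(t(avg))
  p <- file.path(outDir, "bray_curtis.csv")
  utils::write.csv(data.frame(group = rownames(D), D, check.names = FALSE),
                   p, row.names = FALSE)
  paths["bray_curtis"] <- p

  Dsamp <- brayCurtisMatrix(t(Q))
  pm <- permanovaTest(Dsamp, groups, nPerm = config$nPerm,
                      seed = config$seed)
  p <- file.path(outDir, "permanova.json")
  jsonlite::write_json(pm, p, auto_unbox = TRUE, digits = NA)
  paths["permanova"] <- p

  hc <- hclustProfiles(t(Q))
  p <- file.path(outDir, "dendrogram.nwk")
  writeNewick(hc, p)
  paths["dendrogram"] <- p
  paths
}

stageEGA <- function(inputs, outDir, config) {
  run <- readMzML(unlist(inputs$mzml)[1], mode = "ega")
  prog <- TemperatureProgram(config$egaStartTemp, config$egaHold,
                             config$egaRampRate, config$egaEndTemp)
  tic <- egaCurve(run, prog, "TIC")
  co2 <- egaCurve(run, prog, 44)
  paths <- character()
  paths["tic"] <- writeEGACurve(tic, file.path(outDir, "ega_tic.csv"))
  pt <- peakTemperatures(tic)
  p <- file.path(outDir, "ega_peaks.csv")
  utils::write.csv(data.frame(peak_temp_C = pt), p, row.names = FALSE)
  paths["peaks"] <- p
  ht <- highTempFlag(tic, co2, cutoff = config$icCutoff)
  p <- file.path(outDir, "high_temp.json")
  jsonlite::write_json(ht, p, auto_unbox = TRUE, digits = NA)
  paths["high_temp"] <- p
  paths
}
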