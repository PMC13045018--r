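#' @include AllGenerics.R
NULL

# Central S4 data model: spectra, runs, features, libraries, networks,
# EGA curves. Validity methods enforce the invariants the downstream
# numerics rely on (sorted m/z, non-negative intensities, mode-dependent
# scan ranges, degree/threshold bounds on networks).

#' Instrument scan range for an acquisition mode
#'
#' Quadrupole EI acquisitions scan m/z 29--850 in pyrolysis (chromatographic)
#' mode and m/z 29--650 in evolved-gas (EGA) mode; peaks outside the range
#' are instrument artifacts and are dropped on load.
#'
#' @param mode `"pyrolysis"` or `"ega"`.
#' @return Numeric length-2 vector `c(low, high)` in Th.
#' @export
scanRange <- function(mode = c("pyrolysis", "ega")) {
  mode <- match.arg(mode)
  if (mode == "pyrolysis") c(29, 850) else c(29, 650)
}

#' The 12 default pyrolysate compound classes
#'
#' Pyrolysis products of soil organic matter are grouped by chemical
#' structure and likely biopolymer origin into twelve classes: alkenes,
#' degraded saccharides, fatty acids/alcohols/esters, lignin, long alkanes,
#' monocyclic aromatic hydrocarbons (MAH), N-containing MAH (N-MAH), other
#' hydrocarbons, other N-containing compounds, phenols, polycyclic aromatic
#' hydrocarbons (PAH), and short alkanes.
#'
#' @return Character vector of the 12 class names.
#' @export
somClasses <- function() {
  c("alkenes", "degraded saccharides", "fatty acids, alcohols and esters",
    "lignin", "long alkanes", "MAH", "N-MAH", "other hydrocarbons",
    "other N-containing", "phenols", "PAH", "short alkanes")
}

## ---------------------------------------------------------------- Spectrum

#' Spectrum: one EI fragmentation spectrum
#'
#' @slot mz numeric, strictly ascending m/z values (Th).
#' @slot intensity numeric, non-negative abundances, same length as `mz`.
#' @slot rt numeric(1), retention time in minutes (>= 0).
#' @slot metadata named list of free-form strings (instrument, sample id...).
#' @export
setClass("Spectrum",
  slots = c(mz = "numeric", intensity = "numeric", rt = "numeric",
            metadata = "list"),
  prototype = prototype(rt = 0, metadata = list()))

setValidity("Spectrum", function(object) {
  msg <- character()
  if (length(object@mz) < 1L) msg <- c(msg, "spectrum must have at least 1 peak")
  if (length(object@mz) != length(object@intensity))
    msg <- c(msg, "mz and intensity lengths differ")
  if (length(object@mz) > 1L && any(diff(object@mz) <= 0))
    msg <- c(msg, "mz must be strictly ascending")
  if (any(object@intensity < 0)) msg <- c(msg, "intensities must be >= 0")
  if (length(object@rt) != 1L || is.na(object@rt) || object@rt < 0)
    msg <- c(msg, "rt must be a single value >= 0 (minutes)")
  if (length(msg)) msg else TRUE
})

#' Construct a Spectrum
#'
#' @param mz m/z values (Th); sorted ascending if needed.
#' @param intensity non-negative intensities, same length.
#' @param rt retention time in minutes (default 0).
#' @param metadata named list of strings.
#' @return A \linkS4class{Spectrum}.
#' @examples
#' Spectrum(c(91, 65, 39), c(999, 120, 80), rt = 1.5)
#' @export
Spectrum <- function(mz, intensity, rt = 0, metadata = list()) {
  o <- order(mz)
  new("Spectrum", mz = as.numeric(mz[o]), intensity = as.numeric(intensity[o]),
      rt = as.numeric(rt), metadata = metadata)
}

#' @describeIn Spectrum m/z accessor.
#' @param object a Spectrum.
#' @export
setMethod("mz", "Spectrum", function(object) object@mz)

#' @describeIn Spectrum intensity accessor.
#' @export
setMethod("intensity", "Spectrum", function(object) object@intensity)

#' @describeIn Spectrum retention-time accessor (minutes).
#' @export
setMethod("rtime", "Spectrum", function(object) object@rt)

setMethod("show", "Spectrum", function(object) {
  bp <- object@mz[which.max(object@intensity)]
  cat(sprintf("Spectrum: %d peaks, m/z %.0f-%.0f, base peak %.0f, rt %.3f min\n",
              length(object@mz), min(object@mz), max(object@mz), bp, object@rt))
})

## ------------------------------------------------------------------ PyRun

#' PyRun: a time-ordered acquisition
#'
#' A raw GC-EI-MS acquisition: MS1 scans in time order, either in pyrolysis
#' (chromatographic) or EGA (evolved gas, no separation) mode. The mode fixes
#' the permitted scan range (see [scanRange()]).
#'
#' @slot scans list of \linkS4class{Spectrum}, rt non-decreasing.
#' @slot mode `"pyrolysis"` or `"ega"`.
#' @slot scanInterval seconds per scan.
#' @export
setClass("PyRun",
  slots = c(scans = "list", mode = "character", scanInterval = "numeric"))

setValidity("PyRun", function(object) {
  msg <- character()
  if (!object@mode %in% c("pyrolysis", "ega"))
    msg <- c(msg, "mode must be 'pyrolysis' or 'ega'")
  if (!all(vapply(object@scans, is, logical(1), "Spectrum")))
    msg <- c(msg, "all scans must be Spectrum objects")
  else if (length(object@scans)) {
    rts <- vapply(object@scans, function(s) s@rt, numeric(1))
    if (any(diff(rts) < 0)) msg <- c(msg, "scan rts must be non-decreasing")
    rng <- scanRange(object@mode)
    ok <- vapply(object@scans, function(s)
      all(s@mz >= rng[1] & s@mz <= rng[2]), logical(1))
    if (!all(ok))
      msg <- c(msg, sprintf("scan %d has peaks outside the %s scan range [%g, %g]",
                            which(!ok)[1], object@mode, rng[1], rng[2]))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PyRun
#'
#' @param scans list of \linkS4class{Spectrum} in time order.
#' @param mode acquisition mode, `"pyrolysis"` (default) or `"ega"`.
#' @param scanInterval seconds per scan (0.3 s typical for py-GC/MS,
#'   2 s for EGA).
#' @return A \linkS4class{PyRun}.
#' @export
PyRun <- function(scans, mode = c("pyrolysis", "ega"), scanInterval = NA_real_) {
  mode <- match.arg(mode)
  if (is.na(scanInterval) && length(scans) > 1) {
    rts <- vapply(scans, function(s) s@rt, numeric(1))
    scanInterval <- stats::median(diff(rts)) * 60
  }
  new("PyRun", scans = scans, mode = mode, scanInterval = scanInterval)
}

#' @describeIn PyRun scan list accessor.
#' @param object a PyRun.
#' @export
setMethod("scans", "PyRun", function(object) object@scans)

#' @describeIn PyRun acquisition-mode accessor.
#' @export
setMethod("runMode", "PyRun", function(object) object@mode)

#' Scan retention times of a run
#' @param run a \linkS4class{PyRun}.
#' @return Numeric vector of scan rts in minutes.
#' @export
scanTimes <- function(run) vapply(run@scans, function(s) s@rt, numeric(1))

setMethod("show", "PyRun", function(object) {
  n <- length(object@scans)
  if (n) {
    rts <- scanTimes(object)
    cat(sprintf("PyRun (%s): %d MS1 scans, rt %.3f-%.3f min, %.2g s/scan\n",
                object@mode, n, min(rts), max(rts), object@scanInterval))
  } else cat(sprintf("PyRun (%s): empty\n", object@mode))
})

## ------------------------------------------------------------ library types

#' LibraryEntry: one reference spectrum
#'
#' @slot name compound name (non-empty).
#' @slot spectrum the reference \linkS4class{Spectrum} (rt ignored).
#' @slot classHint optional compound class, `NA` if none.
#' @export
setClass("LibraryEntry",
  slots = c(name = "character", spectrum = "Spectrum", classHint = "character"),
  prototype = prototype(classHint = NA_character_))

setValidity("LibraryEntry", function(object) {
  if (length(object@name) != 1L || !nzchar(object@name))
    "name must be a single non-empty string" else TRUE
})

#' Construct a LibraryEntry
#' @param name compound name.
#' @param spectrum reference \linkS4class{Spectrum}.
#' @param classHint optional class name.
#' @return A \linkS4class{LibraryEntry}.
#' @export
LibraryEntry <- function(name, spectrum, classHint = NA_character_)
  new("LibraryEntry", name = name, spectrum = spectrum,
      classHint = as.character(classHint))

#' ClassLibrary: compound name to compound class map
#'
#' @slot entries named character vector: normalized compound name -> class.
#' @slot classes permitted class names (default the 12 of [somClasses()]).
#' @export
setClass("ClassLibrary",
  slots = c(entries = "character", classes = "character"),
  prototype = prototype(entries = stats::setNames(character(), character()),
                        classes = character()))

setValidity("ClassLibrary", function(object) {
  msg <- character()
  if (is.null(names(object@entries)) && length(object@entries))
    msg <- c(msg, "entries must be named by compound")
  bad <- setdiff(unique(object@entries), object@classes)
  if (length(bad))
    msg <- c(msg, paste0("classes not in the permitted set: ",
                         paste(bad, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

setMethod("show", "ClassLibrary", function(object) {
  cat(sprintf("ClassLibrary: %d compounds across %d permitted classes\n",
              length(object@entries), length(object@classes)))
})

## ----------------------------------------------------------------- features

#' EIC: extracted-ion chromatogram on one nominal mass bin
#'
#' @slot mz nominal (unit) mass bin, Th.
#' @slot rts retention times, minutes, strictly increasing.
#' @slot intensities non-negative counts, same length as `rts`.
#' @export
setClass("EIC", slots = c(mz = "numeric", rts = "numeric",
                          intensities = "numeric"))

setValidity("EIC", function(object) {
  msg <- character()
  if (length(object@rts) != length(object@intensities))
    msg <- c(msg, "rts and intensities lengths differ")
  if (length(object@rts) > 1 && any(diff(object@rts) <= 0))
    msg <- c(msg, "rts must be strictly increasing")
  if (any(object@intensities < 0)) msg <- c(msg, "intensities must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Feature: one deconvoluted pyrolysate in one sample
#'
#' @slot rt apex retention time, minutes.
#' @slot spectrum resolved component \linkS4class{Spectrum}
#'   (base peak normalized to 999).
#' @slot height apex intensity of the base-peak ion, counts.
#' @slot area trapezoidal integral of the base-peak elution profile,
#'   counts x min.
#' @slot sampleId sample identifier.
#' @export
setClass("Feature",
  slots = c(rt = "numeric", spectrum = "Spectrum", height = "numeric",
            area = "numeric", sampleId = "character"))

setValidity("Feature", function(object) {
  if (object@height <= 0) "height must be > 0" else TRUE
})

#' Construct a Feature
#' @param rt apex retention time (minutes).
#' @param spectrum resolved \linkS4class{Spectrum}.
#' @param height apex intensity (counts).
#' @param area integrated intensity (counts x min).
#' @param sampleId sample identifier.
#' @return A \linkS4class{Feature}.
#' @export
Feature <- function(rt, spectrum, height, area = NA_real_,
                    sampleId = "sample1")
  new("Feature", rt = as.numeric(rt), spectrum = spectrum,
      height = as.numeric(height), area = as.numeric(area),
      sampleId = sampleId)

#' @describeIn Feature apex retention time (minutes).
#' @param object a Feature.
#' @export
setMethod("rtime", "Feature", function(object) object@rt)

setMethod("show", "Feature", function(object) {
  cat(sprintf("Feature [%s]: rt %.3f min, height %.3g, %d fragments\n",
              object@sampleId, object@rt, object@height,
              length(object@spectrum@mz)))
})

#' AlignedFeature: a cross-sample group of matched features
#'
#' @slot members list of \linkS4class{Feature}, at most one per sample.
#' @slot consensusSpectrum height-weighted mean member spectrum on the
#'   unit-mass grid, base peak 999.
#' @slot rt mean member rt, minutes.
#' @slot perSampleHeight named numeric: sample id -> height (0 where absent).
#' @export
setClass("AlignedFeature",
  slots = c(members = "list", consensusSpectrum = "Spectrum", rt = "numeric",
            perSampleHeight = "numeric"))

setValidity("AlignedFeature", function(object) {
  msg <- character()
  if (!length(object@members)) msg <- c(msg, "members must be non-empty")
  sids <- vapply(object@members, function(f) f@sampleId, character(1))
  if (anyDuplicated(sids))
    msg <- c(msg, "no two members may share a sample id")
  if (length(msg)) msg else TRUE
})

setMethod("show", "AlignedFeature", function(object) {
  cat(sprintf("AlignedFeature: rt %.3f min, %d member(s) [%s]\n",
              object@rt, length(object@members),
              paste(vapply(object@members, function(f) f@sampleId,
                           character(1)), collapse = ", ")))
})

## ---------------------------------------------------------------- network

#' MolecularNetwork: fragmentation-spectrum similarity graph
#'
#' Nodes are consensus spectra (with optional class annotations and
#' per-group abundances); edges connect spectra with cosine similarity at or
#' above the edge threshold that additionally survive mutual-TopK pruning,
#' so every node has degree <= TopK.
#'
#' @slot spectra named list of \linkS4class{Spectrum}, one per node.
#' @slot nodes `data.frame`: nodeId, compound, score, compoundClass,
#'   provenance ("library", "propagated" or NA), degree, singleton.
#' @slot abundance numeric matrix, nodes x groups (ecosystems); may have
#'   zero columns when no grouping is supplied.
#' @slot edges `data.frame`: nodeA, nodeB, cosine (undirected, unique,
#'   nodeA < nodeB).
#' @slot params list with `minCosine` and `topK`.
#' @export
setClass("MolecularNetwork",
  slots = c(spectra = "list", nodes = "data.frame", abundance = "matrix",
            edges = "data.frame", params = "list"))

setValidity("MolecularNetwork", function(object) {
  msg <- character()
  e <- object@edges
  if (nrow(e)) {
    if (any(e$nodeA == e$nodeB)) msg <- c(msg, "self-edges are not allowed")
    key <- paste(pmin(e$nodeA, e$nodeB), pmax(e$nodeA, e$nodeB))
    if (anyDuplicated(key)) msg <- c(msg, "duplicate undirected edges")
    if (!is.null(object@params$minCosine) &&
        any(e$cosine < object@params$minCosine - 1e-12))
      msg <- c(msg, "edge cosine below the network threshold")
    deg <- table(c(e$nodeA, e$nodeB))
    if (!is.null(object@params$topK) && any(deg > object@params$topK))
      msg <- c(msg, "node degree exceeds TopK")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn MolecularNetwork node metadata accessor.
#' @param object a MolecularNetwork.
#' @export
setMethod("nodeData", "MolecularNetwork", function(object) object@nodes)

#' @describeIn MolecularNetwork edge table accessor.
#' @export
setMethod("networkEdges", "MolecularNetwork", function(object) object@edges)

setMethod("show", "MolecularNetwork", function(object) {
  n <- nrow(object@nodes)
  cat(sprintf(paste0("MolecularNetwork: %d nodes (%d singletons), %d edges ",
                     "(cosine >= %.2f, TopK %d)\n"),
              n, sum(object@nodes$singleton), nrow(object@edges),
              object@params$minCosine, object@params$topK))
  if (n) {
    cl <- object@nodes$compoundClass
    cat(sprintf("  classified: %d library, %d propagated, %d unclassified\n",
                sum(object@nodes$provenance %in% "library"),
                sum(object@nodes$provenance %in% "propagated"),
                sum(cl == "unclassified")))
  }
})

## -------------------------------------------------------------------- EGA

#' TemperatureProgram: furnace ramp for EGA
#'
#' Defaults follow the standard evolved-gas protocol: 100 degC start with a
#' 1 min isothermal hold, then 10 degC/min to 900 degC.
#'
#' @slot startTemp degC.
#' @slot hold minutes of initial isothermal hold.
#' @slot rampRate degC per minute (> 0).
#' @slot endTemp degC (> startTemp); temperature is capped here.
#' @export
setClass("TemperatureProgram",
  slots = c(startTemp = "numeric", hold = "numeric", rampRate = "numeric",
            endTemp = "numeric"))

setValidity("TemperatureProgram", function(object) {
  msg <- character()
  if (object@endTemp <= object@startTemp)
    msg <- c(msg, "endTemp must exceed startTemp")
  if (object@rampRate <= 0) msg <- c(msg, "rampRate must be > 0")
  if (object@hold < 0) msg <- c(msg, "hold must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a TemperatureProgram
#' @param startTemp start temperature, degC (default 100).
#' @param hold initial hold, minutes (default 1).
#' @param rampRate ramp, degC/min (default 10).
#' @param endTemp final temperature, degC (default 900).
#' @return A \linkS4class{TemperatureProgram}.
#' @export
TemperatureProgram <- function(startTemp = 100, hold = 1, rampRate = 10,
                               endTemp = 900)
  new("TemperatureProgram", startTemp = startTemp, hold = hold,
      rampRate = rampRate, endTemp = endTemp)

#' EGACurve: evolved-gas intensity versus furnace temperature
#'
#' @slot temps degC, non-decreasing.
#' @slot intensity counts, same length.
#' @slot channel numeric vector of m/z bins summed per scan;
#'   `numeric(0)` means TIC (all bins).
#' @export
setClass("EGACurve",
  slots = c(temps = "numeric", intensity = "numeric", channel = "numeric"))

setValidity("EGACurve", function(object) {
  msg <- character()
  if (length(object@temps) != length(object@intensity))
    msg <- c(msg, "temps and intensity lengths differ")
  if (length(object@temps) > 1 && any(diff(object@temps) < 0))
    msg <- c(msg, "temps must be non-decreasing")
  if (length(msg)) msg else TRUE
})

#' @describeIn EGACurve intensity accessor.
#' @param object an EGACurve.
#' @export
setMethod("intensity", "EGACurve", function(object) object@intensity)

#' Temperature grid of an EGA curve
#' @param curve an \linkS4class{EGACurve}.
#' @return Numeric vector of temperatures (degC).
#' @export
curveTemps <- function(curve) curve@temps

setMethod("show", "EGACurve", function(object) {
  ch <- if (length(object@channel)) paste0("m/z {",
    paste(object@channel, collapse = ", "), "}") else "TIC"
  cat(sprintf("EGACurve (%s): %d points, %.0f-%.0f degC, max %.3g\n",
              ch, length(object@temps), min(object@temps), max(object@temps),
              max(object@intensity)))
})
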