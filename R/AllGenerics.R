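#' Peak m/z values of a spectrum
#'
#' @param object a \linkS4class{Spectrum}.
#' @return Numeric vector of m/z values (Th), ascending.
#' @export
setGeneric("mz", function(object) standardGeneric("mz"))

#' Peak intensities
#'
#' @param object a \linkS4class{Spectrum} or \linkS4class{EGACurve}.
#' @return Numeric vector of non-negative intensities (counts).
#' @export
setGeneric("intensity", function(object) standardGeneric("intensity"))

#' Retention time
#'
#' @param object a \linkS4class{Spectrum} or \linkS4class{Feature}.
#' @return Retention time in minutes.
#' @export
setGeneric("rtime", function(object) standardGeneric("rtime"))

#' Scans of a run
#'
#' @param object a \linkS4class{PyRun}.
#' @return List of \linkS4class{Spectrum}, time ordered.
#' @export
setGeneric("scans", function(object) standardGeneric("scans"))

#' Acquisition mode of a run
#'
#' @param object a \linkS4class{PyRun}.
#' @return `"pyrolysis"` or `"ega"`.
#' @export
setGeneric("runMode", function(object) standardGeneric("runMode"))

#' Spectral cosine similarity
#'
#' Normalized dot product of two electron-ionization fragmentation spectra
#' after projection onto the unit-mass (nominal integer m/z) grid. The value
#' is 1 for proportional spectra, 0 for spectra with disjoint fragments, and
#' lies in \[0, 1\] for non-negative intensities. It is symmetric and
#' invariant to uniform intensity scaling of either spectrum.
#'
#' @param a,b \linkS4class{Spectrum} objects (or named numeric vectors of
#'   intensities keyed by integer m/z).
#' @return Cosine similarity in \[0, 1\].
#' @examples
#' a <- Spectrum(c(50, 77), c(100, 50))
#' b <- Spectrum(c(50, 77), c(50, 100))
#' spectralCosine(a, b)  # 0.8
#' @export
setGeneric("spectralCosine", function(a, b) standardGeneric("spectralCosine"))

#' Node metadata of a molecular network
#'
#' @param object a \linkS4class{MolecularNetwork}.
#' @return `data.frame` with one row per node: `nodeId`, `compound`, `score`,
#'   `compoundClass`, `provenance`, `degree`, `singleton`.
#' @export
setGeneric("nodeData", function(object) standardGeneric("nodeData"))

#' Edge table of a molecular network
#'
#' @param object a \linkS4class{MolecularNetwork}.
#' @return `data.frame` with columns `nodeA`, `nodeB`, `cosine`.
#' @export
setGeneric("networkEdges", function(object) standardGeneric("networkEdges"))
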