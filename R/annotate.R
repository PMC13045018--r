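# Library annotation and compound-class assignment. Matching uses the plain
# (unweighted) cosine on raw intensities over unit-mass bins; an optional
# intensity exponent is exposed for users who want NIST-style weighting.

#' @describeIn spectralCosine cosine between two Spectrum objects.
#' @export
setMethod("spectralCosine", signature("Spectrum", "Spectrum"), function(a, b) {
  va <- binSpectrum(a); vb <- binSpectrum(b)
  cosineVectors(va, vb)
})

#' @describeIn spectralCosine cosine between named intensity vectors
#'   (names are m/z).
#' @export
setMethod("spectralCosine", signature("numeric", "numeric"), function(a, b) {
  cosineVectors(binSpectrum(a), binSpectrum(b))
})

cosineVectors <- function(va, vb) {
  if (sum(va) == 0 || sum(vb) == 0)
    stop("cosine similarity undefined for an all-zero spectrum")
  bins <- union(names(va), names(vb))
  x <- stats::setNames(numeric(length(bins)), bins)
  y <- x
  x[names(va)] <- va; y[names(vb)] <- vb
  val <- sum(x * y) / (sqrt(sum(x^2)) * sqrt(sum(y^2)))
  min(max(val, 0), 1)
}

#' Annotate consensus spectra against a reference library
#'
#' Each node receives its best-scoring library entry when that cosine
#' reaches `minCosine`; otherwise the node stays unannotated (the best score
#' is still reported). Ties are broken by library order.
#'
#' @param nodes list of \linkS4class{AlignedFeature}, list of
#'   \linkS4class{Feature}, or a named list of \linkS4class{Spectrum}.
#' @param library list of \linkS4class{LibraryEntry} (non-empty).
#' @param minCosine minimum cosine to accept an annotation
#'   (0 < c <= 1; default 0.7).
#' @param intensityExponent optional exponent applied to intensities before
#'   matching (default 1 = plain cosine).
#' @return `data.frame` with columns `nodeId`, `rt`, `compound` (`NA` when
#'   unannotated), `score` (best library cosine), `compoundClass`
#'   (initialized to `"unclassified"`; see [assignClasses()]).
#' @export
annotateFeatures <- function(nodes, library, minCosine = 0.7,
                             intensityExponent = 1) {
  if (!length(library)) stop("library must be non-empty")
  if (minCosine <= 0 || minCosine > 1) stop("minCosine must be in (0, 1]")
  spectra <- nodeSpectra(nodes)
  rts <- vapply(spectra, function(s) s@rt, numeric(1))
  libSpectra <- lapply(library, function(e) e@spectrum)
  all <- c(spectra, libSpectra)
  M <- binMatrix(all)^intensityExponent
  Mn <- M / sqrt(rowSums(M^2))
  ns <- length(spectra)
  S <- Mn[seq_len(ns), , drop = FALSE] %*%
    t(Mn[ns + seq_along(libSpectra), , drop = FALSE])
  best <- apply(S, 1, which.max)           # first max = library order
  bestScore <- S[cbind(seq_len(ns), best)]
  libNames <- vapply(library, function(e) e@name, character(1))
  data.frame(
    nodeId = names(spectra),
    rt = rts,
    compound = ifelse(bestScore >= minCosine, libNames[best], NA_character_),
    score = pmin(pmax(bestScore, 0), 1),
    compoundClass = "unclassified",
    stringsAsFactors = FALSE)
}

# Coerce supported node containers to a named list of Spectrum.
nodeSpectra <- function(nodes) {
  if (is(nodes, "Spectrum")) nodes <- list(nodes)
  spectra <- lapply(nodes, function(x) {
    if (is(x, "AlignedFeature")) x@consensusSpectrum
    else if (is(x, "Feature")) x@spectrum
    else if (is(x, "Spectrum")) x
    else stop("unsupported node type: ", class(x)[1])
  })
  if (is.null(names(spectra)) || any(!nzchar(names(spectra))))
    names(spectra) <- paste0("AF", seq_along(spectra))
  spectra
}

#' Map annotated compounds to compound classes
#'
#' Annotated compounds present in the class library receive that class;
#' annotated-but-unlisted compounds and unannotated nodes become
#' `"unclassified"`. Input order, compound names and scores are preserved;
#' the operation is idempotent.
#'
#' @param annotations `data.frame` from [annotateFeatures()].
#' @param classes a \linkS4class{ClassLibrary}.
#' @return The annotations with `compoundClass` filled in and a
#'   `provenance` column (`"library"` for class-library assignments, `NA`
#'   otherwise).
#' @export
assignClasses <- function(annotations, classes) {
  cls <- rep("unclassified", nrow(annotations))
  has <- !is.na(annotations$compound)
  cls[has] <- classLookup(classes, annotations$compound[has])
  annotations$compoundClass <- cls
  annotations$provenance <- ifelse(cls != "unclassified", "library",
                                   NA_character_)
  annotations
}

#' Export annotations as delimited text
#'
#' @param annotations annotation `data.frame` (see [assignClasses()]).
#' @param quant optional quantification matrix from [quantificationTable()];
#'   per-sample heights are appended by nodeId.
#' @param path output path (comma-separated).
#' @return The exported `data.frame`, invisibly.
#' @export
writeAnnotations <- function(annotations, path, quant = NULL) {
  out <- annotations
  if (!is.null(quant)) {
    idx <- match(out$nodeId, rownames(quant))
    out <- cbind(out, as.data.frame(quant[idx, , drop = FALSE],
                                    check.names = FALSE))
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(out)
}
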