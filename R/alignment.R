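# Cross-sample feature alignment. The pair score blends a retention-time
# term and spectral cosine: score = wRt * max(0, 1 - |dRT|/rtTol) +
# (1 - wRt) * cosine. Groups are grown greedily from the best-scoring pair;
# a pair below the score threshold is never merged, and a group holds at
# most one feature per sample.

#' Align deconvoluted features across samples
#'
#' @param features either a flat list of \linkS4class{Feature} (sample ids
#'   taken from the features) or a list of per-sample feature lists.
#' @param scoreThreshold minimum pair score to merge (0 < t <= 1;
#'   default 0.7).
#' @param rtTol retention-time tolerance in minutes (default 0.05); beyond
#'   it the RT term of the score is 0.
#' @param wRt weight of the RT term (0 to 1; default 0.5).
#' @return List of \linkS4class{AlignedFeature}, ordered by rt, covering
#'   every input feature exactly once (unmatched features become
#'   singleton groups).
#' @details Merging is deterministic: candidate pairs are processed in
#'   descending score, ties broken by lower mean rt then lexicographic
#'   sample-id pair. Two groups merge only when their sample sets are
#'   disjoint. The consensus spectrum is the height-weighted mean of the
#'   member spectra on the unit-mass grid, rescaled to base peak 999.
#' @export
alignFeatures <- function(features, scoreThreshold = 0.7, rtTol = 0.05,
                          wRt = 0.5) {
  if (scoreThreshold <= 0 || scoreThreshold > 1)
    stop("scoreThreshold must be in (0, 1]")
  if (rtTol <= 0) stop("rtTol must be > 0")
  if (wRt < 0 || wRt > 1) stop("wRt must be in [0, 1]")
  if (length(features) && is.list(features[[1]]) &&
      !is(features[[1]], "Feature"))
    features <- unlist(features, recursive = FALSE)
  n <- length(features)
  if (!n) return(list())
  rts <- vapply(features, rtime, numeric(1))
  sids <- vapply(features, function(f) f@sampleId, character(1))
  M <- binMatrix(lapply(features, function(f) f@spectrum))
  Mn <- M / sqrt(rowSums(M^2))

  # candidate pairs: different samples, rt close enough that the score can
  # clear the threshold even at cosine 1
  cand <- NULL
  if (n > 1) {
    cos <- tcrossprod(Mn)
    ij <- which(upper.tri(cos), arr.ind = TRUE)
    drt <- abs(rts[ij[, 1]] - rts[ij[, 2]])
    score <- wRt * pmax(0, 1 - drt / rtTol) +
      (1 - wRt) * pmin(pmax(cos[ij], 0), 1)
    ok <- score >= scoreThreshold & sids[ij[, 1]] != sids[ij[, 2]]
    if (any(ok)) {
      cand <- data.frame(i = ij[ok, 1], j = ij[ok, 2], score = score[ok])
      cand$meanRt <- (rts[cand$i] + rts[cand$j]) / 2
      a <- pmin(sids[cand$i], sids[cand$j])
      b <- pmax(sids[cand$i], sids[cand$j])
      cand <- cand[order(-cand$score, cand$meanRt, a, b), , drop = FALSE]
    }
  }

  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  groupSamples <- lapply(seq_len(n), function(i) sids[i])
  if (!is.null(cand)) for (k in seq_len(nrow(cand))) {
    ri <- find(cand$i[k]); rj <- find(cand$j[k])
    if (ri == rj) next
    if (length(intersect(groupSamples[[ri]], groupSamples[[rj]]))) next
    parent[rj] <- ri
    groupSamples[[ri]] <- c(groupSamples[[ri]], groupSamples[[rj]])
  }
  roots <- vapply(seq_len(n), find, integer(1))
  allSamples <- sort(unique(sids))
  groups <- split(seq_len(n), roots)
  out <- lapply(groups, function(ii) {
    mem <- features[ii]
    h <- vapply(mem, function(f) f@height, numeric(1))
    cons <- colSums(M[ii, , drop = FALSE] * h) / sum(h)
    keep <- cons > 0
    cmz <- as.numeric(colnames(M))[keep]
    ci <- cons[keep] / max(cons[keep]) * 999
    psh <- stats::setNames(numeric(length(allSamples)), allSamples)
    psh[sids[ii]] <- h
    new("AlignedFeature", members = mem,
        consensusSpectrum = Spectrum(cmz, ci, rt = mean(rts[ii])),
        rt = mean(rts[ii]), perSampleHeight = psh)
  })
  out <- unname(out)
  out[order(vapply(out, function(g) g@rt, numeric(1)))]
}

#' Quantification table of aligned features
#'
#' @param aligned list of \linkS4class{AlignedFeature}.
#' @param path optional path to write the table as comma-separated text.
#' @return Numeric matrix, aligned features (rows, named `AF1`, `AF2`, ...
#'   in rt order) x samples (columns), holding per-sample heights with 0
#'   where a sample lacks the feature.
#' @export
quantificationTable <- function(aligned, path = NULL) {
  if (!length(aligned)) return(matrix(numeric(), 0, 0))
  samples <- sort(unique(unlist(lapply(aligned, function(g)
    names(g@perSampleHeight)))))
  Q <- matrix(0, length(aligned), length(samples),
              dimnames = list(paste0("AF", seq_along(aligned)), samples))
  for (k in seq_along(aligned)) {
    h <- aligned[[k]]@perSampleHeight
    Q[k, names(h)] <- h
  }
  if (!is.null(path))
    utils::write.csv(data.frame(nodeId = rownames(Q), Q, check.names = FALSE),
                     path, row.names = FALSE)
  Q
}

#' Consensus spectra of aligned features
#'
#' @param aligned list of \linkS4class{AlignedFeature}.
#' @return Named list of \linkS4class{Spectrum} (`AF1`, `AF2`, ... in the
#'   input order), suitable for [writeMGF()] and [buildNetwork()].
#' @export
consensusSpectra <- function(aligned) {
  stats::setNames(lapply(aligned, function(g) g@consensusSpectrum),
                  paste0("AF", seq_along(aligned)))
}
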