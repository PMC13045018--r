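# Chromatogram construction and spectral deconvolution. EICs are built on
# unit-mass bins (EI quadrupole data and reference libraries are nominal
# mass); co-eluting components inside an RT window are separated by
# window-wise non-negative alternating least squares (MCR-ALS) initialized
# from the apex-scan spectra.

#' Build extracted-ion chromatograms from a run
#'
#' Bins every scan onto the unit-mass grid and keeps one EIC per integer m/z
#' bin that reaches the intensity threshold (default 1e5 counts) in at least
#' one scan. The threshold gates the existence of an EIC, not its points:
#' sub-threshold points inside a kept EIC are retained. Every EIC shares the
#' run's full scan-time grid (zero where the bin is absent from a scan),
#' which the downstream curve-resolution step relies on.
#'
#' @param run a pyrolysis-mode \linkS4class{PyRun}.
#' @param intensityThreshold minimum single-scan intensity for a bin to
#'   produce an EIC (counts, > 0; default 1e5).
#' @return List of \linkS4class{EIC}, ordered by m/z. Empty run gives an
#'   empty list.
#' @export
buildEICs <- function(run, intensityThreshold = 1e5) {
  if (!is.numeric(intensityThreshold) || intensityThreshold <= 0)
    stop("intensityThreshold must be > 0")
  if (runMode(run) != "pyrolysis")
    stop("buildEICs expects a pyrolysis-mode run")
  sc <- run@scans
  if (!length(sc)) return(list())
  rts <- scanTimes(run)
  binned <- lapply(sc, binSpectrum)
  bins <- sort(unique(as.integer(unlist(lapply(binned, names)))))
  M <- matrix(0, length(sc), length(bins),
              dimnames = list(NULL, as.character(bins)))
  for (k in seq_along(binned)) M[k, names(binned[[k]])] <- binned[[k]]
  keep <- which(apply(M, 2, max) >= intensityThreshold)
  lapply(keep, function(j)
    new("EIC", mz = bins[j], rts = rts, intensities = M[, j]))
}

#' Detect chromatographic peaks in one EIC
#'
#' Local maxima are kept when the apex height reaches `minHeight` and the
#' signal-to-noise ratio reaches `minSN`. Noise is estimated robustly as
#' 1.4826 x the median absolute deviation of the first difference of the
#' trace, divided by sqrt(2) -- the first difference cancels the slowly
#' varying chromatographic signal so the estimate is dominated by
#' point-to-point noise even when the trace contains peaks. Peak bounds are
#' the nearest flanking local minima.
#'
#' @param eic an \linkS4class{EIC}.
#' @param minSN minimum signal-to-noise ratio (>= 1; default 5).
#' @param minHeight minimum apex intensity (counts, > 0; default 1e5).
#' @return `data.frame` with one row per peak: `mz`, `apexRt`, `height`,
#'   `apexIdx`, `leftIdx`, `rightIdx`, `leftRt`, `rightRt`. Zero rows when
#'   the trace has no qualifying peak.
#' @export
detectPeaks <- function(eic, minSN = 5, minHeight = 1e5) {
  if (minSN < 1) stop("minSN must be >= 1")
  if (minHeight <= 0) stop("minHeight must be > 0")
  y <- eic@intensities
  idx <- localMaxima(y)
  empty <- data.frame(mz = numeric(), apexRt = numeric(), height = numeric(),
                      apexIdx = integer(), leftIdx = integer(),
                      rightIdx = integer(), leftRt = numeric(),
                      rightRt = numeric())
  if (!length(idx)) return(empty)
  noise <- stats::mad(diff(y)) / sqrt(2)
  keep <- y[idx] >= minHeight & (noise == 0 | y[idx] / noise >= minSN)
  idx <- idx[keep]
  if (!length(idx)) return(empty)
  n <- length(y)
  mins <- c(1L, localMinima(y), n)
  bounds <- t(vapply(idx, function(i) {
    l <- max(mins[mins <= i]); r <- min(mins[mins >= i])
    c(l, r)
  }, integer(2)))
  data.frame(mz = eic@mz, apexRt = eic@rts[idx], height = y[idx],
             apexIdx = idx, leftIdx = bounds[, 1], rightIdx = bounds[, 2],
             leftRt = eic@rts[bounds[, 1]], rightRt = eic@rts[bounds[, 2]])
}

localMinima <- function(y) {
  n <- length(y)
  if (n < 3) return(integer())
  which(y[2:(n - 1)] < y[1:(n - 2)] & y[2:(n - 1)] <= y[3:n]) + 1L
}

#' Resolve co-eluting components by non-negative ALS
#'
#' Detected peaks across all EICs are clustered by apex retention time
#' (single linkage; a gap larger than `rtTol` starts a new window). Inside a
#' window the scans x m/z intensity matrix `X` is factorized as
#' `X ~ C %*% t(S)` with non-negative elution profiles `C` and component
#' spectra `S` by alternating least squares (negative parts clipped after
#' each unconstrained solve). The number of components is the number of
#' distinct apex sub-clusters inside the window (apexes closer than about
#' 1.5 scan intervals are one component, since fragments of one compound
#' apex together). `S` is initialized from the apex-scan spectra, which
#' makes the factorization deterministic. Iteration stops when the relative
#' residual changes by less than `tol` or after `maxIter` iterations (with a
#' warning); an iterate that increases the residual is rolled back, so the
#' residual trace is non-increasing.
#'
#' Each component yields one \linkS4class{Feature}: its spectrum is the
#' corresponding column of `S` normalized to base peak 999, its rt and
#' height come from the apex of its elution profile (height is the apex
#' intensity of the base-peak ion, area its trapezoidal integral), and
#' components below `minHeight` are discarded.
#'
#' @param eics list of \linkS4class{EIC} on a shared rt grid
#'   (from [buildEICs()]).
#' @param peaks list of peak tables parallel to `eics` (from
#'   [detectPeaks()]), or `NULL` to detect with defaults.
#' @param rtTol retention-time tolerance in minutes separating components
#'   (> 0; default 0.05).
#' @param minHeight minimum feature height (counts; default 1e5).
#' @param minSN passed to [detectPeaks()] when `peaks` is `NULL`.
#' @param sampleId sample id stamped on the features.
#' @param smooth moving-average window (scans) applied to the EIC traces of
#'   each window before factorization (default 5, 1 disables). Temporal
#'   smoothing is linear in time, so component spectra are unchanged; it
#'   suppresses the scan-to-scan noise floor the low-rank model cannot fit.
#' @param maxIter,tol ALS stopping controls.
#' @return List of \linkS4class{Feature}, ordered by rt, with the per-window
#'   relative ALS reconstruction errors in the `"residuals"` attribute.
#' @export
resolveComponents <- function(eics, peaks = NULL, rtTol = 0.05,
                              minHeight = 1e5, minSN = 5,
                              sampleId = "sample1", smooth = 5,
                              maxIter = 200, tol = 1e-6) {
  if (rtTol <= 0) stop("rtTol must be > 0")
  if (!length(eics)) return(list())
  if (is.null(peaks))
    peaks <- lapply(eics, detectPeaks, minSN = minSN, minHeight = minHeight)
  pk <- do.call(rbind, lapply(seq_along(eics), function(k) {
    p <- peaks[[k]]
    if (!nrow(p)) return(NULL)
    p$eic <- k
    p
  }))
  if (is.null(pk) || !nrow(pk)) return(list())
  rts <- eics[[1]]@rts
  scanGap <- if (length(rts) > 1) stats::median(diff(rts)) else rtTol
  # fragments of one compound apex within a couple of scans of each other;
  # genuinely distinct components are farther apart than that but may sit
  # inside one rtTol window
  apexTol <- max(2.5 * scanGap, rtTol / 5)

  pk <- pk[order(pk$apexRt), , drop = FALSE]
  windowId <- cumsum(c(1, diff(pk$apexRt) > rtTol))
  feats <- list()
  residuals <- numeric()
  ssRes <- 0; ssX <- 0
  for (w in unique(windowId)) {
    pw <- pk[windowId == w, , drop = FALSE]
    # anchor-based apex clustering: tall peaks found components, remaining
    # peaks join the nearest anchor within apexTol; avoids single-linkage
    # chaining across two components whose fragment apexes jitter
    ord <- order(-pw$height, pw$apexRt)
    anchors <- numeric(0)
    comp <- integer(nrow(pw))
    for (i in ord) {
      if (length(anchors)) {
        dd <- abs(pw$apexRt[i] - anchors)
        j <- which.min(dd)
        if (dd[j] <= apexTol) { comp[i] <- j; next }
      }
      anchors <- c(anchors, pw$apexRt[i])
      comp[i] <- length(anchors)
    }
    # scan window: union of peak bounds, capped at the apex range +- rtTol
    # so the tails of compounds in neighboring windows do not leak in
    loRt <- min(pw$apexRt) - rtTol; hiRt <- max(pw$apexRt) + rtTol
    lo <- max(1L, min(pw$leftIdx) - 2L, which(rts >= loRt)[1])
    hi <- min(length(rts), max(pw$rightIdx) + 2L,
              utils::tail(which(rts <= hiRt), 1))
    win <- lo:hi
    # model only EICs with evidence inside this window: bins carrying a
    # detected peak here, or substantial sub-threshold signal; leaving out
    # the noise-only bins keeps the factorization well-conditioned
    allMz <- vapply(eics, function(e) e@mz, numeric(1))
    winMax <- vapply(eics, function(e) max(e@intensities[win]), numeric(1))
    useCol <- allMz %in% pw$mz | winMax >= 0.2 * minHeight
    X <- vapply(eics[useCol], function(e) e@intensities[win],
                numeric(length(win)))              # scans x bins
    if (smooth > 1) X <- apply(X, 2, movingAverage, window = smooth)
    mzBins <- allMz[useCol]
    # apex scan (by tallest member peak) per component
    apexIdx <- vapply(split(seq_len(nrow(pw)), comp), function(ii)
      pw$apexIdx[ii][which.max(pw$height[ii])], integer(1))
    initRows <- apexIdx - lo + 1L
    # tails of compounds outside the window leak in at its edges; model them
    # as discardable edge components so they do not distort the real spectra
    tot <- rowSums(X)
    nW <- length(win)
    edgeRows <- integer()
    if (tot[1] > 0.05 * max(tot)) edgeRows <- c(edgeRows, 1L)
    if (tot[nW] > 0.05 * max(tot)) edgeRows <- c(edgeRows, nW)
    nReal <- length(initRows)
    S0 <- t(X[c(initRows, edgeRows), , drop = FALSE])  # bins x k
    fit <- mcrALS(X, S0, maxIter = maxIter, tol = tol)
    residuals <- c(residuals, fit$residual)
    ssRes <- ssRes + (fit$residual * fit$normX)^2
    ssX <- ssX + fit$normX^2
    for (j in seq_len(nReal)) {
      s <- fit$S[, j]; cprof <- fit$C[, j]
      if (max(s) <= 0 || max(cprof) <= 0) next
      if (which.max(cprof) %in% c(1L, nW)) next   # edge tail, not a peak
      bp <- max(s)
      ints <- s / bp * 999
      keep <- ints >= 1
      if (!any(keep)) next
      apex <- which.max(cprof)
      height <- max(cprof) * bp
      if (height < minHeight) next
      feats[[length(feats) + 1L]] <- Feature(
        rt = rts[win][apex],
        spectrum = Spectrum(mzBins[keep], ints[keep], rt = rts[win][apex]),
        height = height,
        area = trapz(rts[win], cprof * bp),
        sampleId = sampleId)
    }
  }
  feats <- feats[order(vapply(feats, rtime, numeric(1)))]
  # per-window relative reconstruction errors, plus the run-level relative
  # residual (all windows pooled; norm-weighted, so the abundant signal
  # dominates as it does in the raw data)
  attr(feats, "residuals") <- residuals
  attr(feats, "residual") <- if (ssX > 0) sqrt(ssRes / ssX) else NA_real_
  feats
}

# Non-negative ALS: X (scans x bins) ~ C (scans x k) %*% t(S) (bins x k).
# Returns C, S, the residual trace, and a convergence flag. An update that
# would increase the residual is rolled back and iteration stops, so the
# recorded residual trace is non-increasing.
mcrALS <- function(X, S0, maxIter = 200, tol = 1e-6) {
  S <- pmax(S0, 0)
  normX <- sqrt(sum(X^2))
  if (normX == 0) stop("all-zero window matrix")
  C <- matrix(0, nrow(X), ncol(S))
  res <- Inf; trace <- numeric(); converged <- FALSE
  for (it in seq_len(maxIter)) {
    Cn <- pmax(X %*% S %*% ridgeInv(crossprod(S)), 0)
    Sn <- pmax(crossprod(X, Cn) %*% ridgeInv(crossprod(Cn)), 0)
    newRes <- sqrt(sum((X - Cn %*% t(Sn))^2)) / normX
    if (newRes > res + 1e-12) {
      # residual stopped decreasing: keep the previous (best) iterate
      converged <- TRUE
      break
    }
    C <- Cn; S <- Sn
    trace <- c(trace, newRes)
    if (newRes < 1e-9 ||
        (is.finite(res) && abs(res - newRes) < tol * max(newRes, 1e-12))) {
      res <- newRes; converged <- TRUE; break
    }
    res <- newRes
  }
  if (!converged)
    warning("MCR-ALS did not converge in ", maxIter,
            " iterations; best iterate returned")
  list(C = C, S = S, residual = res, trace = trace, converged = converged,
       normX = normX)
}

ridgeInv <- function(A) {
  eps <- 1e-10 * mean(diag(A)) + 1e-300
  solve(A + diag(eps, nrow(A)))
}

#' One-call deconvolution of a run
#'
#' Convenience wrapper: [buildEICs()], [detectPeaks()] and
#' [resolveComponents()] with shared parameters.
#'
#' @param run a pyrolysis-mode \linkS4class{PyRun}.
#' @param intensityThreshold EIC existence threshold (default 1e5 counts).
#' @param minSN minimum peak signal-to-noise (default 5).
#' @param minHeight minimum feature height (default 1e5 counts).
#' @param rtTol component retention-time tolerance (default 0.05 min).
#' @param sampleId sample id stamped on the features (defaults to the run's
#'   `sample` metadata when present).
#' @return List of \linkS4class{Feature}.
#' @export
deconvolve <- function(run, intensityThreshold = 1e5, minSN = 5,
                       minHeight = 1e5, rtTol = 0.05, sampleId = NULL) {
  if (is.null(sampleId)) {
    sampleId <- "sample1"
    if (length(run@scans)) {
      md <- run@scans[[1]]@metadata
      if (!is.null(md$sample)) sampleId <- md$sample
    }
  }
  eics <- buildEICs(run, intensityThreshold)
  resolveComponents(eics, rtTol = rtTol, minHeight = minHeight,
                    minSN = minSN, sampleId = sampleId)
}

#' Export a feature table
#'
#' @param features list of \linkS4class{Feature}.
#' @param path optional path; when given, the table is written as
#'   comma-separated text.
#' @return `data.frame` with sample_id, rt_min, height, area, base_peak_mz,
#'   n_fragments.
#' @export
featureTable <- function(features, path = NULL) {
  df <- data.frame(
    sample_id = vapply(features, function(f) f@sampleId, character(1)),
    rt_min = vapply(features, rtime, numeric(1)),
    height = vapply(features, function(f) f@height, numeric(1)),
    area = vapply(features, function(f) f@area, numeric(1)),
    base_peak_mz = vapply(features, function(f)
      f@spectrum@mz[which.max(f@spectrum@intensity)], numeric(1)),
    n_fragments = vapply(features, function(f)
      length(f@spectrum@mz), integer(1)))
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}
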