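# Internal helpers shared across modules.

# Evaluate expr with a temporary RNG state seeded at `seed`; the caller's
# RNG stream is untouched.
withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Project a Spectrum (or named intensity vector) onto the unit-mass grid:
# returns intensities named by integer m/z, duplicate bins summed.
binSpectrum <- function(s) {
  if (is(s, "Spectrum")) {
    m <- round(s@mz); i <- s@intensity
  } else {
    m <- round(as.numeric(names(s))); i <- as.numeric(s)
  }
  v <- vapply(split(i, m), sum, numeric(1))
  v
}

# Stack a list of spectra into a dense nodes x bins intensity matrix on the
# shared unit-mass grid.
binMatrix <- function(spectra) {
  binned <- lapply(spectra, binSpectrum)
  bins <- sort(unique(as.integer(unlist(lapply(binned, names)))))
  M <- matrix(0, length(binned), length(bins),
              dimnames = list(names(spectra), as.character(bins)))
  for (k in seq_along(binned)) M[k, names(binned[[k]])] <- binned[[k]]
  M
}

# All pairwise cosine similarities between rows of a binned matrix.
cosineMatrix <- function(M) {
  nrm <- sqrt(rowSums(M^2))
  if (any(nrm == 0)) stop("cosine similarity undefined for an all-zero spectrum")
  S <- tcrossprod(M / nrm)
  S[S > 1] <- 1; S[S < 0] <- 0
  S
}

# Case-insensitive, whitespace-normalized compound key used for class lookup;
# CAS-style trailing qualifiers after " # " or ", cas" are stripped.
normalizeCompound <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("\\s*#.*$", "", x)
  x <- gsub(",?\\s*cas(\\s|-)?(no\\.?|number)?\\s*[0-9-]*$", "", x)
  gsub("\\s+", " ", x)
}

# Trapezoidal integral.
trapz <- function(x, y) {
  if (length(x) < 2) return(0)
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

# Moving average with shrinking windows at the edges (no NA padding).
movingAverage <- function(y, window) {
  if (window <= 1) return(y)
  n <- length(y); half <- floor(window / 2)
  cs <- cumsum(c(0, y))
  lo <- pmax(seq_len(n) - half, 1); hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# Indices of strict local maxima (plateau-left convention: rises before,
# does not rise after).
localMaxima <- function(y) {
  n <- length(y)
  if (n < 3) return(integer())
  which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
}
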