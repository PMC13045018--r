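# Independent brute-force oracles used to check the package implementations.

# cosine on explicit m/z -> intensity maps via direct summation
oracleCosine <- function(a, b) {
  bins <- sort(union(names(a), names(b)))
  x <- y <- setNames(numeric(length(bins)), bins)
  x[names(a)] <- a; y[names(b)] <- b
  sum(x * y) / sqrt(sum(x^2) * sum(y^2))
}

# connected components by plain union-find on an edge list
oracleComponents <- function(ids, edges) {
  parent <- setNames(ids, ids)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (nrow(edges)) for (k in seq_len(nrow(edges))) {
    ra <- find(edges$nodeA[k]); rb <- find(edges$nodeB[k])
    if (ra != rb) parent[rb] <- ra
  }
  roots <- vapply(ids, find, character(1))
  touched <- unique(c(edges$nodeA, edges$nodeB))
  comps <- split(ids, roots)
  comps <- comps[vapply(comps, function(cc) any(cc %in% touched), logical(1))]
  unname(lapply(comps, sort))
}

# mutual-TopK pruning computed directly from the full similarity matrix
oracleMutualTopK <- function(S, ids, minCosine, topK) {
  n <- nrow(S)
  diag(S) <- -Inf
  topOf <- lapply(seq_len(n), function(i)
    order(-S[i, ], seq_len(n))[seq_len(min(topK, n - 1))])
  keep <- NULL
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (S[i, j] >= minCosine && j %in% topOf[[i]] && i %in% topOf[[j]])
      keep <- rbind(keep, data.frame(nodeA = ids[i], nodeB = ids[j],
                                     cosine = S[i, j]))
  if (is.null(keep)) data.frame(nodeA = character(), nodeB = character(),
                                cosine = numeric())
  else keep
}

# step-by-step average-linkage agglomeration returning the cophenetic matrix
oracleAverageLinkCophenetic <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  d <- D
  active <- seq_along(clusters)
  while (length(active) > 1) {
    best <- c(NA, NA); bd <- Inf
    for (ai in seq_along(active)) for (aj in seq_len(ai - 1)) {
      i <- active[ai]; j <- active[aj]
      dd <- mean(D[clusters[[i]], clusters[[j]]])
      if (dd < bd) { bd <- dd; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    coph[clusters[[i]], clusters[[j]]] <- bd
    coph[clusters[[j]], clusters[[i]]] <- bd
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    active <- setdiff(active, j)
  }
  coph
}

# pseudo-F over all balanced two-group label assignments of a 6-sample matrix
oracleExhaustiveP <- function(D, groups) {
  n <- nrow(D)
  ga <- which(groups == levels(factor(groups))[1])
  Fof <- function(lab) permanovaTest(D, lab, nPerm = 1)$pseudoF
  Fobs <- Fof(groups)
  assignments <- combn(n, length(ga))
  Fs <- apply(assignments, 2, function(ii) {
    l <- rep("b", n); l[ii] <- "a"; Fof(l)
  })
  mean(Fs >= Fobs - 1e-12)
}

# tiny deterministic spectrum constructors
toySpectrum <- function(mzI, rt = 0) Spectrum(as.numeric(names(mzI)),
                                              as.numeric(mzI), rt = rt)

toyFeature <- function(mzI, rt, height, sampleId = "s1")
  Feature(rt, toySpectrum(mzI, rt), height, sampleId = sampleId)
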