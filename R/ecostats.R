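# Ecological statistics on pyrolysate abundance profiles: class relative
# abundance, Shannon and Gini-Simpson diversity, Bray-Curtis dissimilarity,
# distance-based PERMANOVA with a permutation p-value, average-linkage
# hierarchical clustering of log-transformed abundances, and Pearson
# correlation between ecosystem compound profiles.

#' Class relative abundance per sample
#'
#' Per sample, the share of each compound class is the summed height of its
#' classified features divided by the summed height of all classified
#' features; shares sum to 1. Unclassified features are excluded. Samples
#' with zero classified abundance are dropped with a warning. When
#' `replicateGroups` is given, replicate shares are averaged (mean).
#'
#' @param quant quantification matrix (features x samples), e.g. from
#'   [quantificationTable()].
#' @param featureClasses class per feature row (`"unclassified"` excluded).
#' @param replicateGroups optional factor over samples; shares are averaged
#'   within each level.
#' @param classes class set defining the output columns (default
#'   [somClasses()]).
#' @return Matrix samples (or replicate groups) x classes; rows sum to 1.
#' @export
classRelativeAbundance <- function(quant, featureClasses,
                                   replicateGroups = NULL,
                                   classes = somClasses()) {
  stopifnot(nrow(quant) == length(featureClasses))
  keep <- featureClasses != "unclassified" & !is.na(featureClasses)
  q <- quant[keep, , drop = FALSE]
  fc <- factor(featureClasses[keep], levels = classes)
  agg <- apply(q, 2, function(col) tapply(col, fc, sum, default = 0))
  agg <- matrix(agg, nrow = length(classes),
                dimnames = list(classes, colnames(quant)))
  tot <- colSums(agg)
  if (any(tot == 0)) {
    warning("sample(s) with zero classified abundance excluded: ",
            paste(colnames(agg)[tot == 0], collapse = ", "))
    agg <- agg[, tot > 0, drop = FALSE]
    tot <- tot[tot > 0]
  }
  shares <- t(agg) / tot
  if (!is.null(replicateGroups)) {
    g <- factor(replicateGroups)[match(rownames(shares), colnames(quant))]
    g <- droplevels(g)
    shares <- apply(shares, 2, function(col) tapply(col, g, mean))
    shares <- matrix(shares, ncol = length(classes),
                     dimnames = list(levels(g), classes))
  }
  shares
}

checkShares <- function(p) {
  if (!length(p)) stop("empty share vector")
  if (any(p < 0)) stop("shares must be non-negative")
  s <- sum(p)
  if (s == 0) stop("share vector sums to zero")
  if (abs(s - 1) > 1e-8) {
    warning("shares do not sum to 1; renormalizing")
    p <- p / s
  }
  p
}

#' Shannon diversity index
#'
#' H = -sum p_i ln p_i, with 0 ln 0 taken as 0. Computed over compound
#' shares (not classes) when characterizing pyrolysate diversity; any
#' non-normalized non-negative vector is renormalized with a warning.
#'
#' @param p share vector (non-negative, summing to 1).
#' @return H, between 0 (single compound) and ln(length(p)) (uniform).
#' @examples
#' shannonIndex(rep(0.25, 4))  # log(4)
#' @export
shannonIndex <- function(p) {
  p <- checkShares(p)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Gini-Simpson diversity index
#'
#' 1 - sum p_i^2: the probability that two randomly drawn pyrolysate ions
#' belong to different compounds. Larger values mean more diverse; a single
#' compound gives 0 and a uniform profile over S compounds gives 1 - 1/S.
#'
#' @param p share vector (non-negative, summing to 1).
#' @return Index in [0, 1 - 1/length(p)].
#' @export
simpsonIndex <- function(p) {
  p <- checkShares(p)
  1 - sum(p^2)
}

#' Bray-Curtis dissimilarity
#'
#' sum |x_i - y_i| / sum (x_i + y_i); 0 for identical profiles, 1 for
#' disjoint supports; symmetric.
#'
#' @param x,y non-negative abundance vectors of equal length, not both
#'   all-zero.
#' @return Dissimilarity in [0, 1].
#' @export
brayCurtis <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (any(x < 0) || any(y < 0)) stop("abundances must be non-negative")
  denom <- sum(x + y)
  if (denom == 0) stop("Bray-Curtis undefined: both vectors all-zero")
  sum(abs(x - y)) / denom
}

#' Bray-Curtis distance matrix
#'
#' @param table abundance matrix, samples x compounds.
#' @return Symmetric matrix of pairwise Bray-Curtis dissimilarities.
#' @export
brayCurtisMatrix <- function(table) {
  n <- nrow(table)
  D <- matrix(0, n, n, dimnames = list(rownames(table), rownames(table)))
  for (i in seq_len(n)) for (j in seq_len(n)) if (j > i)
    D[i, j] <- D[j, i] <- brayCurtis(table[i, ], table[j, ])
  D
}

#' Distance-based PERMANOVA
#'
#' One-factor permutational multivariate analysis of variance on a distance
#' matrix. With n samples in a groups and squared distances d^2:
#' SS_total = sum_{i<j} d_ij^2 / n; SS_within = sum over groups g of
#' sum_{i<j in g} d_ij^2 / n_g; SS_between = SS_total - SS_within;
#' pseudo-F = (SS_between/(a-1)) / (SS_within/(n-a)); R^2 =
#' SS_between/SS_total. The p-value is (1 + #\{F* >= F\}) / (1 + nPerm) over
#' whole-row label permutations. Labels are permuted freely (no strata).
#'
#' @param d distance matrix (or `dist`), symmetric with zero diagonal.
#' @param groups factor of group labels, >= 2 groups.
#' @param nPerm number of permutations (default 999).
#' @param seed integer seed for the permutation stream (the caller's RNG
#'   state is untouched); `NULL` uses the current stream.
#' @return List with `pseudoF`, `R2`, `p`, `nPerm`, `df` (c(a-1, n-a)).
#' @export
permanovaTest <- function(d, groups, nPerm = 999, seed = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8)) ||
      any(abs(diag(d)) > 1e-12))
    stop("d must be symmetric with zero diagonal")
  groups <- factor(groups)
  a <- nlevels(groups)
  if (a < 2) stop("need at least 2 groups")
  if (length(groups) != n) stop("groups length must match d")
  if (n - a < 1) stop("degrees-of-freedom error: need n > number of groups")
  if (nPerm < 1) stop("nPerm must be >= 1")
  d2 <- d^2
  ssTotal <- sum(d2[upper.tri(d2)]) / n
  fstat <- function(lab) {
    ssw <- 0
    for (g in levels(lab)) {
      idx <- which(lab == g)
      if (length(idx) > 1)
        ssw <- ssw + sum(d2[idx, idx]) / 2 / length(idx)
    }
    ssb <- ssTotal - ssw
    (ssb / (a - 1)) / (ssw / (n - a))
  }
  Fobs <- fstat(groups)
  doPerm <- function() {
    Fperm <- vapply(seq_len(nPerm), function(k)
      fstat(groups[sample.int(n)]), numeric(1))
    (1 + sum(Fperm >= Fobs - 1e-12)) / (1 + nPerm)
  }
  p <- if (is.null(seed)) doPerm() else withSeed(seed, doPerm())
  sswObs <- 0
  for (g in levels(groups)) {
    idx <- which(groups == g)
    if (length(idx) > 1) sswObs <- sswObs + sum(d2[idx, idx]) / 2 / length(idx)
  }
  list(pseudoF = Fobs, R2 = (ssTotal - sswObs) / ssTotal, p = p,
       nPerm = nPerm, df = c(between = a - 1, within = n - a))
}

#' Hierarchical clustering of abundance profiles
#'
#' Profiles are ln(x+1)-transformed (handles zeros), pairwise Bray-Curtis
#' dissimilarities are computed, and samples are agglomerated by average
#' linkage. Merge order is deterministic; exact ties are resolved by
#' `stats::hclust`'s ordering (first pair in row-major order), which on
#' continuous data never fires.
#'
#' @param table abundance matrix, samples x compounds (>= 2 samples).
#' @return An object of class `hclust`.
#' @seealso [writeNewick()]
#' @export
hclustProfiles <- function(table) {
  if (nrow(table) < 2) stop("need at least 2 samples to cluster")
  D <- brayCurtisMatrix(log1p(table))
  stats::hclust(stats::as.dist(D), method = "average")
}

#' Export a dendrogram in Newick format
#'
#' @param hc an `hclust` object (see [hclustProfiles()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeNewick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Pearson correlation between compound profiles
#'
#' Profiles are matched on the union of their compound names (absent
#' compounds counted as 0) and the sample Pearson correlation with its
#' two-sided t-test p-value is returned.
#'
#' @param x,y named abundance vectors (compound -> abundance); unnamed
#'   vectors of equal length are used as-is.
#' @return List with `r` and `p`.
#' @export
pearsonProfiles <- function(x, y) {
  if (!is.null(names(x)) && !is.null(names(y))) {
    cmp <- union(names(x), names(y))
    xx <- stats::setNames(numeric(length(cmp)), cmp)
    yy <- xx
    xx[names(x)] <- x; yy[names(y)] <- y
    x <- xx; y <- yy
  } else if (length(x) != length(y))
    stop("unnamed vectors must have equal length")
  if (length(x) < 3) stop("need at least 3 compounds")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}
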