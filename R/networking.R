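# Fragmentation-spectrum molecular networking: pairwise cosine, edge
# threshold, mutual-TopK pruning (an edge survives only if each endpoint
# ranks the other within its TopK most similar neighbors, which bounds every
# node's degree by TopK), singleton exclusion, connected-component clusters,
# and single-pass class propagation from annotated neighbors.

#' Build a molecular network from annotated consensus spectra
#'
#' All pairwise cosines are computed on the unit-mass grid; candidate edges
#' with cosine at or above `minCosine` are kept only when each endpoint
#' ranks the other within its `topK` most similar candidates (mutual TopK),
#' so the degree of every node is at most `topK`. Nodes left without an edge
#' are flagged singletons and excluded from cluster output.
#'
#' @param nodes list of \linkS4class{AlignedFeature} or a named list of
#'   \linkS4class{Spectrum}.
#' @param annotations annotation `data.frame` from [assignClasses()]
#'   (matched by `nodeId`); optional.
#' @param abundance optional numeric matrix of per-group (e.g. ecosystem)
#'   abundances, rows matched to node ids.
#' @param minCosine minimum edge cosine (default 0.7).
#' @param topK maximum neighbors per node (default 10).
#' @return A \linkS4class{MolecularNetwork}. Fewer than 2 nodes give an
#'   empty (edgeless) network.
#' @export
buildNetwork <- function(nodes, annotations = NULL, abundance = NULL,
                         minCosine = 0.7, topK = 10) {
  if (minCosine <= 0 || minCosine > 1) stop("minCosine must be in (0, 1]")
  if (topK < 1) stop("topK must be >= 1")
  spectra <- nodeSpectra(nodes)
  ids <- names(spectra)
  n <- length(ids)
  nd <- data.frame(nodeId = ids, compound = NA_character_, score = NA_real_,
                   compoundClass = "unclassified",
                   provenance = NA_character_, stringsAsFactors = FALSE)
  if (!is.null(annotations)) {
    idx <- match(ids, annotations$nodeId)
    hit <- !is.na(idx)
    nd$compound[hit] <- annotations$compound[idx[hit]]
    nd$score[hit] <- annotations$score[idx[hit]]
    if (!is.null(annotations$compoundClass))
      nd$compoundClass[hit] <- annotations$compoundClass[idx[hit]]
    if (!is.null(annotations$provenance))
      nd$provenance[hit] <- annotations$provenance[idx[hit]]
    else nd$provenance[nd$compoundClass != "unclassified"] <- "library"
  }
  ab <- if (is.null(abundance)) matrix(numeric(), n, 0,
                                       dimnames = list(ids, NULL))
  else {
    stopifnot(nrow(abundance) == n)
    if (is.null(rownames(abundance))) rownames(abundance) <- ids
    abundance[ids, , drop = FALSE]
  }
  edges <- data.frame(nodeA = character(), nodeB = character(),
                      cosine = numeric(), stringsAsFactors = FALSE)
  if (n >= 2) {
    S <- cosineMatrix(binMatrix(spectra))
    diag(S) <- -Inf
    edges <- mutualTopKEdges(S, ids, minCosine, topK)
  }
  deg <- stats::setNames(integer(n), ids)
  if (nrow(edges)) {
    t1 <- table(c(edges$nodeA, edges$nodeB))
    deg[names(t1)] <- as.integer(t1)
  }
  nd$degree <- unname(deg)
  nd$singleton <- nd$degree == 0L
  new("MolecularNetwork", spectra = spectra, nodes = nd, abundance = ab,
      edges = edges, params = list(minCosine = minCosine, topK = topK))
}

# Mutual-TopK pruning on a full similarity matrix (diag = -Inf). Ranks are
# taken in descending similarity with ties broken by node order, so the
# result is deterministic.
mutualTopKEdges <- function(S, ids, minCosine, topK) {
  n <- nrow(S)
  rank <- matrix(NA_integer_, n, n)
  for (i in seq_len(n)) {
    o <- order(-S[i, ], seq_len(n))
    rank[i, o] <- seq_len(n)
  }
  ij <- which(upper.tri(S) & S >= minCosine, arr.ind = TRUE)
  if (!nrow(ij))
    return(data.frame(nodeA = character(), nodeB = character(),
                      cosine = numeric(), stringsAsFactors = FALSE))
  keep <- rank[ij] <= topK & rank[ij[, c(2, 1), drop = FALSE]] <= topK
  ij <- ij[keep, , drop = FALSE]
  data.frame(nodeA = ids[ij[, 1]], nodeB = ids[ij[, 2]],
             cosine = S[ij], stringsAsFactors = FALSE)
}

#' Clusters of a molecular network
#'
#' Connected components of the pruned graph, excluding singleton nodes,
#' ordered by decreasing size with ties broken by smallest node id.
#'
#' @param net a \linkS4class{MolecularNetwork}.
#' @return List of character vectors of node ids (each sorted).
#' @export
networkClusters <- function(net) {
  e <- net@edges
  if (!nrow(e)) return(list())
  g <- igraph::graph_from_data_frame(e[, c("nodeA", "nodeB")],
                                     directed = FALSE)
  comp <- igraph::components(g)
  out <- lapply(split(names(comp$membership), comp$membership), sort)
  out <- unname(out)
  sz <- vapply(out, length, integer(1))
  first <- vapply(out, `[`, character(1), 1)
  out[order(-sz, first)]
}

#' Propagate compound classes to unannotated nodes
#'
#' Single pass: every unclassified node with at least one originally
#' classified neighbor receives the class of its highest-cosine such
#' neighbor (ties: higher total abundance, then lexicographic node id).
#' Originally classified labels never change; nodes with no classified
#' neighbor stay unclassified. Propagated labels carry provenance
#' `"propagated"`. With `chain = TRUE` the pass is repeated, letting labels
#' travel through previously propagated nodes, until no node changes.
#'
#' @param net a \linkS4class{MolecularNetwork} with annotations.
#' @param chain allow chained propagation through propagated labels
#'   (default `FALSE`).
#' @return The network with updated `compoundClass`/`provenance`.
#' @export
propagateClasses <- function(net, chain = FALSE) {
  repeat {
    nd <- net@nodes
    totAb <- if (ncol(net@abundance)) rowSums(net@abundance)
    else stats::setNames(numeric(nrow(nd)), nd$nodeId)
    e <- net@edges
    classified <- nd$compoundClass != "unclassified"
    names(classified) <- nd$nodeId
    newClass <- nd$compoundClass
    changed <- FALSE
    for (i in which(!classified)) {
      id <- nd$nodeId[i]
      nb <- rbind(
        data.frame(other = e$nodeB[e$nodeA == id],
                   cosine = e$cosine[e$nodeA == id]),
        data.frame(other = e$nodeA[e$nodeB == id],
                   cosine = e$cosine[e$nodeB == id]))
      nb <- nb[classified[nb$other], , drop = FALSE]
      if (!nrow(nb)) next
      nb <- nb[order(-nb$cosine, -totAb[nb$other], nb$other), , drop = FALSE]
      newClass[i] <- nd$compoundClass[match(nb$other[1], nd$nodeId)]
      net@nodes$provenance[i] <- "propagated"
      changed <- TRUE
    }
    net@nodes$compoundClass <- newClass
    if (!chain || !changed) break
  }
  net
}

#' Ecosystem distribution of network nodes
#'
#' Per node, the share of its total abundance contributed by each group
#' (ecosystem); shares sum to 1. Also counts in how many ecosystems each
#' node is present (share > 0) and how many nodes are present in exactly k
#' ecosystems.
#'
#' @param net a \linkS4class{MolecularNetwork} built with an abundance
#'   matrix, or such a matrix directly (rows = nodes, cols = groups).
#' @return List with `shares` (matrix, rows sum to 1; `NA` rows for
#'   zero-abundance nodes), `nEcosystems` (integer per node),
#'   `presenceCounts` (named vector: k -> number of nodes present in
#'   exactly k ecosystems), and `zeroAbundance` (node ids with no signal
#'   anywhere, flagged rather than silently normalized).
#' @export
ecosystemDistribution <- function(net) {
  ab <- if (is(net, "MolecularNetwork")) net@abundance else as.matrix(net)
  if (!ncol(ab)) stop("no abundance groups available")
  tot <- rowSums(ab)
  shares <- ab / tot
  shares[tot == 0, ] <- NA_real_
  nEco <- as.integer(rowSums(ab > 0))
  nEco[tot == 0] <- NA_integer_
  pc <- table(factor(nEco[!is.na(nEco)], levels = seq_len(ncol(ab))))
  list(shares = shares,
       nEcosystems = stats::setNames(nEco, rownames(ab)),
       presenceCounts = stats::setNames(as.integer(pc), names(pc)),
       zeroAbundance = rownames(ab)[tot == 0])
}

#' Export the network edge list
#'
#' @param net a \linkS4class{MolecularNetwork}.
#' @param path output path (tab-separated: node_a, node_b, cosine).
#' @return `path`, invisibly.
#' @export
writeEdgeList <- function(net, path) {
  e <- net@edges
  names(e) <- c("node_a", "node_b", "cosine")
  utils::write.table(e, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export the network as GraphML
#'
#' Node attributes carried: compound, score, compoundClass, provenance,
#' degree; edge attribute: cosine. Suitable for external graph viewers.
#'
#' @param net a \linkS4class{MolecularNetwork}.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGraphML <- function(net, path) {
  nd <- net@nodes
  g <- igraph::graph_from_data_frame(
    net@edges[, c("nodeA", "nodeB", "cosine")],
    directed = FALSE, vertices = within(nd, {
      compound <- ifelse(is.na(compound), "", compound)
      provenance <- ifelse(is.na(provenance), "", provenance)
      score <- ifelse(is.na(score), 0, score)
    }))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
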