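randomSpectra <- function(n, nFamilies, seed) {
  cmp <- genCompoundSet(n, nFamilies = nFamilies, seed = seed)
  setNames(lapply(cmp, `[[`, "spectrum"),
           paste0("N", sprintf("%03d", seq_len(n))))
}

test_that("identical spectra form a fully connected clique", {
  s <- Spectrum(c(50, 77, 91), c(100, 40, 999))
  net <- buildNetwork(list(A = s, B = s, C = s))
  e <- networkEdges(net)
  expect_equal(nrow(e), 3)
  expect_true(all(abs(e$cosine - 1) < 1e-12))
})

test_that("pairs below the edge threshold become singletons", {
  a <- Spectrum(c(50, 77), c(999, 500))
  b <- Spectrum(c(50, 91), c(999, 900))
  cs <- spectralCosine(a, b)
  expect_lt(cs, 0.7)
  net <- buildNetwork(list(A = a, B = b), minCosine = 0.7)
  expect_equal(nrow(networkEdges(net)), 0)
  expect_true(all(nodeData(net)$singleton))
  expect_identical(networkClusters(net), list())
})

test_that("mutual-TopK pruning agrees with the brute-force oracle", {
  for (seed in c(3, 9)) {
    spectra <- randomSpectra(40, nFamilies = 5, seed = seed)
    net <- buildNetwork(spectra, minCosine = 0.7, topK = 4)
    S <- pyrosom:::cosineMatrix(pyrosom:::binMatrix(spectra))
    oe <- oracleMutualTopK(S, names(spectra), 0.7, 4)
    e <- networkEdges(net)
    key <- function(d) sort(paste(pmin(d$nodeA, d$nodeB),
                                  pmax(d$nodeA, d$nodeB)))
    expect_identical(key(e), key(oe))
    # degree bound and edge-threshold bound
    expect_true(all(nodeData(net)$degree <= 4))
    if (nrow(e)) expect_gte(min(e$cosine), 0.7)
  }
})

test_that("near-identical spectra respect the TopK degree bound", {
  set.seed(15)
  base <- genCompound(1, family = 1)$spectrum
  spectra <- setNames(lapply(1:15, function(k)
    Spectrum(mz(base), intensity(base) * exp(rnorm(length(mz(base)),
                                                   0, 0.02)))),
    paste0("N", sprintf("%02d", 1:15)))
  net <- buildNetwork(spectra, minCosine = 0.7, topK = 10)
  expect_true(all(nodeData(net)$degree <= 10))
  S <- pyrosom:::cosineMatrix(pyrosom:::binMatrix(spectra))
  oe <- oracleMutualTopK(S, names(spectra), 0.7, 10)
  expect_equal(nrow(networkEdges(net)), nrow(oe))
})

test_that("clusters equal union-find components, singletons excluded", {
  for (seed in c(21, 22)) {
    spectra <- randomSpectra(30, nFamilies = 6, seed = seed)
    net <- buildNetwork(spectra)
    cl <- networkClusters(net)
    oc <- oracleComponents(nodeData(net)$nodeId, networkEdges(net))
    expect_setequal(vapply(cl, paste, character(1), collapse = "|"),
                    vapply(oc, paste, character(1), collapse = "|"))
    # ordering: decreasing size, then smallest node id
    sz <- vapply(cl, length, integer(1))
    expect_true(all(diff(sz) <= 0))
    singles <- nodeData(net)$nodeId[nodeData(net)$singleton]
    expect_false(any(singles %in% unlist(cl)))
  }
})

test_that("class propagation takes the most similar annotated neighbor", {
  s1 <- Spectrum(c(50, 77, 91), c(999, 400, 100))
  s2 <- Spectrum(c(50, 77, 91), c(950, 430, 120))   # cosine ~1 to s1
  s3 <- Spectrum(c(50, 77, 105), c(999, 380, 300))
  ann <- data.frame(nodeId = c("A", "B", "C"),
                    compound = c("2,6-dimethoxy-phenol", NA, "Syringol-alt"),
                    score = c(0.95, 0.4, 0.9),
                    compoundClass = c("lignin", "unclassified", "phenols"),
                    provenance = c("library", NA, "library"),
                    stringsAsFactors = FALSE)
  net <- buildNetwork(list(A = s1, B = s2, C = s3), ann)
  pr <- propagateClasses(net)
  nd <- nodeData(pr)
  bCos <- networkEdges(net)
  ab <- bCos$cosine[(bCos$nodeA == "A" & bCos$nodeB == "B") |
                    (bCos$nodeA == "B" & bCos$nodeB == "A")]
  bc <- bCos$cosine[(bCos$nodeA == "C" & bCos$nodeB == "B") |
                    (bCos$nodeA == "B" & bCos$nodeB == "C")]
  expect_gt(ab, bc)   # A is the most similar annotated neighbor
  expect_equal(nd$compoundClass[nd$nodeId == "B"], "lignin")
  expect_equal(nd$provenance[nd$nodeId == "B"], "propagated")
  # annotated labels never change
  expect_equal(nd$compoundClass[nd$nodeId == "A"], "lignin")
  expect_equal(nd$provenance[nd$nodeId == "A"], "library")
})

test_that("an isolated unclassified cluster stays unclassified", {
  s <- genCompound(5, family = 2)$spectrum
  ann <- data.frame(nodeId = c("A", "B"), compound = NA_character_,
                    score = 0.2, compoundClass = "unclassified",
                    provenance = NA_character_, stringsAsFactors = FALSE)
  net <- buildNetwork(list(A = s, B = s), ann)
  nd <- nodeData(propagateClasses(net))
  expect_true(all(nd$compoundClass == "unclassified"))
})

test_that("propagation recovers hidden planted labels at >= 90%", {
  cmp <- genCompoundSet(60, nFamilies = 3, seed = 51)
  spectra <- setNames(lapply(cmp, `[[`, "spectrum"),
                      paste0("N", sprintf("%02d", seq_along(cmp))))
  truth <- vapply(cmp, `[[`, character(1), "compoundClass")
  ann <- data.frame(nodeId = names(spectra),
                    compound = vapply(cmp, `[[`, character(1), "name"),
                    score = 1, compoundClass = truth,
                    provenance = "library", stringsAsFactors = FALSE)
  set.seed(52)
  hide <- sample(length(cmp), length(cmp) / 2)
  ann$compoundClass[hide] <- "unclassified"
  ann$compound[hide] <- NA
  ann$provenance[hide] <- NA
  net <- buildNetwork(spectra, ann)
  before <- sum(nodeData(net)$compoundClass == "unclassified")
  pr <- propagateClasses(net)
  nd <- nodeData(pr)
  after <- sum(nd$compoundClass == "unclassified")
  expect_lt(after, before)                       # strictly decreases
  prop <- nd$provenance %in% "propagated"
  expect_gte(mean(nd$compoundClass[prop] ==
                  truth[match(nd$nodeId[prop], names(spectra))]), 0.9)
  # originally annotated labels untouched
  keep <- setdiff(seq_along(cmp), hide)
  expect_equal(nd$compoundClass[match(names(spectra)[keep], nd$nodeId)],
               truth[keep])
})

test_that("ecosystem shares row-normalize and flag empty nodes", {
  ab <- rbind(N1 = c(vernal = 3, prairie = 1, forest = 0),
              N2 = c(vernal = 0, prairie = 0, forest = 5),
              N3 = c(vernal = 0, prairie = 0, forest = 0))
  ed <- ecosystemDistribution(ab)
  expect_equal(unname(ed$shares["N1", ]), c(0.75, 0.25, 0))
  expect_equal(unname(ed$nEcosystems[c("N1", "N2")]), c(2L, 1L))
  expect_equal(ed$zeroAbundance, "N3")
  expect_equal(unname(ed$presenceCounts), c(1L, 1L, 0L))
  # random tables match direct normalization
  set.seed(61)
  R <- matrix(rexp(40), 8, dimnames = list(paste0("n", 1:8), NULL))
  expect_equal(ecosystemDistribution(R)$shares, R / rowSums(R))
})

test_that("degree and threshold bounds hold across random networks", {
  for (seed in c(71, 72, 73)) {
    spectra <- randomSpectra(25, nFamilies = 4, seed = seed)
    for (k in c(2, 5)) {
      net <- buildNetwork(spectra, minCosine = 0.6, topK = k)
      expect_true(all(nodeData(net)$degree <= k))
      e <- networkEdges(net)
      if (nrow(e)) expect_gte(min(e$cosine), 0.6)
    }
  }
})
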