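test_that("diversity indices match their closed forms and bounds", {
  expect_equal(shannonIndex(rep(0.25, 4)), log(4))
  expect_equal(shannonIndex(1), 0)
  expect_equal(shannonIndex(c(0.5, 0.25, 0.25)), 1.5 * log(2))
  expect_equal(simpsonIndex(1), 0)
  expect_equal(simpsonIndex(rep(0.25, 4)), 0.75)
  expect_equal(simpsonIndex(c(0.5, 0.25, 0.25)), 0.625)
  expect_error(shannonIndex(numeric()), "empty")
  expect_warning(h <- shannonIndex(c(2, 2)), "renormaliz")
  expect_equal(h, log(2))
  # analytic bounds on random profiles, cross-checked against vegan
  set.seed(3)
  for (rep in 1:10) {
    S <- sample(2:30, 1)
    p <- rexp(S); p <- p / sum(p)
    H <- shannonIndex(p); G <- simpsonIndex(p)
    expect_gte(H, 0); expect_lte(H, log(S) + 1e-12)
    expect_gte(G, 0); expect_lte(G, 1 - 1 / S + 1e-12)
    expect_equal(H, unname(vegan::diversity(p, "shannon")))
    expect_equal(G, unname(vegan::diversity(p, "simpson")))
  }
})

test_that("Bray-Curtis matches the formula and vegan", {
  expect_equal(brayCurtis(c(1, 2), c(1, 2)), 0)
  expect_equal(brayCurtis(c(1, 0), c(0, 2)), 1)
  expect_equal(brayCurtis(c(1, 2), c(2, 1)), 1 / 3)
  expect_error(brayCurtis(c(0, 0), c(0, 0)), "all-zero")
  set.seed(8)
  X <- matrix(rlnorm(5 * 12), 5)
  D <- brayCurtisMatrix(X)
  expect_equal(D, as.matrix(vegan::vegdist(X, "bray")),
               ignore_attr = TRUE)
})

test_that("class relative abundance row-normalizes classified heights", {
  Q <- rbind(F1 = c(s1 = 300), F2 = c(s1 = 100))
  shares <- classRelativeAbundance(Q, c("lignin", "phenols"))
  expect_equal(unname(shares["s1", c("lignin", "phenols")]), c(0.75, 0.25))
  expect_equal(sum(shares), 1)
  # all features one class
  s2 <- classRelativeAbundance(Q, c("MAH", "MAH"))
  expect_equal(unname(s2["s1", "MAH"]), 1)
  # random tables: rows sum to 1 within 1e-12; unclassified excluded
  set.seed(9)
  Qr <- matrix(rlnorm(60), 12, 5,
               dimnames = list(NULL, paste0("s", 1:5)))
  cls <- sample(c(somClasses()[1:4], "unclassified"), 12, replace = TRUE)
  sr <- classRelativeAbundance(Qr, cls)
  expect_true(all(abs(rowSums(sr) - 1) < 1e-12))
  # replicate averaging
  sra <- classRelativeAbundance(Qr, cls,
                                replicateGroups = c("a", "a", "b", "b", "b"))
  expect_equal(nrow(sra), 2)
  expect_true(all(abs(rowSums(sra) - 1) < 1e-12))
})

test_that("PERMANOVA matches adonis2 and the exhaustive oracle", {
  set.seed(14)
  X <- matrix(rlnorm(12 * 25), 12)
  D <- as.matrix(vegan::vegdist(X, "bray"))
  g <- rep(c("a", "b"), each = 6)
  mine <- permanovaTest(D, g, nPerm = 499, seed = 7)
  ref <- vegan::adonis2(stats::as.dist(D) ~ g, permutations = 499)
  expect_equal(mine$pseudoF, ref$F[1], tolerance = 1e-10)
  expect_equal(mine$R2, ref$R2[1], tolerance = 1e-10)

  # 6-sample toy matrix: permutation p equals exhaustive enumeration
  D6 <- as.matrix(stats::dist(matrix(rnorm(18), 6)))
  g6 <- rep(c("a", "b"), each = 3)
  pEx <- oracleExhaustiveP(D6, g6)
  mine6 <- permanovaTest(D6, g6, nPerm = 9999, seed = 11)
  expect_equal(mine6$p, pEx, tolerance = 0.05)

  # maximally separated groups: R2 -> 1, p at the permutation floor
  Y <- rbind(matrix(rnorm(15, 0, 0.01), 5), matrix(rnorm(15, 50, 0.01), 5))
  Dy <- as.matrix(stats::dist(Y))
  gy <- rep(c("a", "b"), each = 5)
  sep <- permanovaTest(Dy, gy, nPerm = 199, seed = 3)
  expect_gt(sep$R2, 0.99)
  expect_equal(sep$p, 1 / 200, tolerance = 0.01)

  expect_error(permanovaTest(D6, rep("a", 6), 99), "2 groups")
  expect_error(permanovaTest(D6[1:2, 1:2], c("a", "b"), 99),
               "degrees-of-freedom")
})

test_that("null PERMANOVA p-values are approximately uniform", {
  set.seed(20)
  ps <- vapply(1:200, function(k) {
    D <- as.matrix(stats::dist(matrix(rnorm(12 * 4), 12)))
    permanovaTest(D, rep(c("a", "b"), each = 6), nPerm = 99)$p
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("hierarchical clustering reproduces brute-force average linkage", {
  # duplicated samples merge first at height 0
  X <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(9, 0, 1))
  hc <- hclustProfiles(X)
  expect_equal(hc$height[1], 0)
  expect_setequal(hc$labels[hc$merge[1, ] * -1], c("a", "b"))
  # two blocks with disjoint compounds split at the top
  Y <- rbind(a1 = c(5, 6, 0, 0), a2 = c(6, 5, 0, 0),
             b1 = c(0, 0, 7, 8), b2 = c(0, 0, 8, 7))
  hcY <- hclustProfiles(Y)
  top <- stats::cutree(hcY, 2)
  expect_equal(unname(top), c(1, 1, 2, 2))
  # cophenetic distances equal the step-by-step oracle
  set.seed(33)
  Z <- matrix(rlnorm(6 * 10), 6, dimnames = list(paste0("s", 1:6), NULL))
  hcZ <- hclustProfiles(Z)
  coph <- as.matrix(stats::cophenetic(hcZ))
  oracle <- oracleAverageLinkCophenetic(brayCurtisMatrix(log1p(Z)))
  expect_equal(unname(coph), unname(oracle), tolerance = 1e-12)
  expect_error(hclustProfiles(Z[1, , drop = FALSE]), "2 samples")
})

test_that("profile correlation matches the covariance formula", {
  x <- c(A = 1, B = 4, C = 2, D = 8, E = 5)
  y <- c(A = 2, B = 9, C = 3, D = 16, E = 11)
  out <- pearsonProfiles(x, y)
  rOracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(out$r, rOracle)
  expect_equal(pearsonProfiles(x, 2 * x)$r, 1)
  # union-of-compounds matching fills absences with zero
  out2 <- pearsonProfiles(c(A = 1, B = 2, C = 3), c(B = 2, C = 3, D = 4))
  expect_equal(out2$r, stats::cor(c(1, 2, 3, 0), c(0, 2, 3, 4)))
  expect_error(pearsonProfiles(c(A = 1, B = 1, C = 1), x[1:3]), "variance")
})
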