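test_that("EIC existence is gated by the intensity threshold, points are not", {
  mkScan <- function(rt, i91, i120) Spectrum(c(91, 120), c(i91, i120), rt = rt)
  prof <- c(1e4, 8e4, 2e5, 8e4, 1e4)          # m/z 91 crosses 1e5
  low <- prof / 4                              # m/z 120 tops out at 5e4
  run <- PyRun(lapply(1:5, function(k) mkScan((k - 1) * 0.005,
                                              prof[k], low[k])), "pyrolysis")
  eics <- buildEICs(run, intensityThreshold = 1e5)
  expect_length(eics, 1)
  expect_equal(eics[[1]]@mz, 91)
  # sub-threshold points inside the kept EIC survive
  expect_equal(eics[[1]]@intensities, prof)
  expect_error(buildEICs(run, 0), "> 0")
  expect_identical(buildEICs(PyRun(list(), "pyrolysis")), list())
})

test_that("every planted fragment above threshold yields an EIC", {
  g <- genRun(genCompoundSet(5, seed = 2), seed = 3)
  eics <- buildEICs(g$run)
  got <- vapply(eics, function(e) e@mz, numeric(1))
  for (cp in g$compounds) {
    apexContrib <- cp$height * cp$spectrum@intensity / 999
    # 5% margin: the scan grid samples the elution Gaussian slightly off-apex
    need <- round(cp$spectrum@mz[apexContrib >= 1.05e5])
    expect_true(all(need %in% got))
  }
})

test_that("peak detection respects height and S/N gates", {
  rts <- seq(0, 0.5, by = 0.005)
  flat <- new("EIC", mz = 91, rts = rts, intensities = rep(0, length(rts)))
  expect_equal(nrow(detectPeaks(flat)), 0)

  gauss <- function(apex) apex * exp(-(rts - 0.25)^2 / (2 * 0.02^2))
  set.seed(41)
  noisy <- pmax(gauss(5e5) + rnorm(length(rts), 0, 1e3), 0)
  pk <- detectPeaks(new("EIC", mz = 91, rts = rts, intensities = noisy))
  expect_equal(nrow(pk), 1)
  expect_lte(abs(pk$apexRt - 0.25), 0.005)     # within one scan

  small <- detectPeaks(new("EIC", mz = 91, rts = rts,
                           intensities = gauss(5e4)), minHeight = 1e5)
  expect_equal(nrow(small), 0)                 # below the 1e5 height floor
  expect_error(detectPeaks(flat, minSN = 0.5), ">= 1")
})

test_that("disjoint-fragment compounds 0.2 min apart resolve exactly", {
  a <- list(name = "A", spectrum = Spectrum(c(50, 77, 91), c(300, 600, 999)),
            rt = 0.5, height = 1e6, compoundClass = "MAH", family = 1)
  b <- list(name = "B", spectrum = Spectrum(c(60, 94, 107), c(999, 700, 200)),
            rt = 0.7, height = 8e5, compoundClass = "phenols", family = 2)
  g <- genRun(list(a, b), noiseSd = 0, seed = 1)
  feats <- deconvolve(g$run)
  expect_length(feats, 2)
  expect_equal(spectralCosine(feats[[1]]@spectrum, a$spectrum), 1,
               tolerance = 1e-6)
  expect_equal(spectralCosine(feats[[2]]@spectrum, b$spectrum), 1,
               tolerance = 1e-6)
  expect_equal(intensity(feats[[1]]@spectrum), c(300, 600, 999),
               tolerance = 1e-6)
})

test_that("overlapping co-elution at 0.03 min separates with cosine >= 0.95", {
  a <- genCompound(11, family = 1); a$rt <- 1.00; a$height <- 1.2e6
  b <- genCompound(12, family = 1); b$rt <- 1.03; b$height <- 9e5
  g <- genRun(list(a, b), noiseSd = 1e3, seed = 5)
  feats <- suppressWarnings(deconvolve(g$run))
  expect_length(feats, 2)
  expect_gte(spectralCosine(feats[[1]]@spectrum, a$spectrum), 0.95)
  expect_gte(spectralCosine(feats[[2]]@spectrum, b$spectrum), 0.95)
})

test_that("single-compound window reconstructs with residual < 1%", {
  cp <- genCompound(21, family = 3); cp$rt <- 0.5
  g <- genRun(list(cp), noiseSd = 0, seed = 1)
  eics <- buildEICs(g$run)
  pk <- lapply(eics, detectPeaks)
  rts <- eics[[1]]@rts
  X <- vapply(eics, function(e) e@intensities, numeric(length(rts)))
  S0 <- t(X[which.max(rowSums(X)), , drop = FALSE])
  fit <- pyrosom:::mcrALS(X, S0)
  expect_lt(fit$residual, 0.01)
  feats <- resolveComponents(eics, pk)
  expect_length(feats, 1)
})

test_that("ALS iterates stay non-negative with non-increasing residual", {
  set.seed(7)
  for (rep in 1:5) {
    C0 <- cbind(dnorm(1:40, 15, 4), dnorm(1:40, 22, 4))
    S0 <- matrix(runif(2 * 12), 12)
    X <- pmax(C0 %*% t(S0) * 1e6 + matrix(rnorm(40 * 12, 0, 1e3), 40), 0)
    init <- t(X[c(15, 22), , drop = FALSE])
    # slow convergence on heavily overlapped noisy factors is expected here;
    # the property under test is monotonicity and non-negativity
    fit <- suppressWarnings(pyrosom:::mcrALS(X, init))
    expect_true(all(fit$C >= 0))
    expect_true(all(fit$S >= 0))
    expect_true(all(diff(fit$trace) <= 1e-12))
  }
})

test_that("synthetic runs are recovered at >= 90% with cosine >= 0.95", {
  # low noise (<= 1% of apex), mixed planted co-elution
  cmp <- genCompoundSet(12, seed = 8)
  minH <- min(vapply(cmp, `[[`, numeric(1), "height"))
  g <- genRun(cmp, noiseSd = 0.01 * minH, coElutePairs = 3, seed = 9)
  feats <- suppressWarnings(deconvolve(g$run))
  rec <- vapply(seq_along(cmp), function(k) {
    best <- 0
    for (f in feats) if (abs(f@rt - g$truth$rt[k]) < 0.05)
      best <- max(best, spectralCosine(g$compounds[[k]]$spectrum, f@spectrum))
    best
  }, numeric(1))
  expect_gte(mean(rec >= 0.95), 0.9)
  # component count matches the planted count for separations >= 0.02 min
  expect_equal(length(feats), length(cmp))
})
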