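test_that("Spectrum enforces its invariants", {
  s <- Spectrum(c(91, 39, 65), c(999, 80, 120), rt = 1.2)
  expect_equal(mz(s), c(39, 65, 91))          # sorted on construction
  expect_equal(intensity(s), c(80, 120, 999))
  expect_error(new("Spectrum", mz = numeric(), intensity = numeric(),
                   rt = 0, metadata = list()), "at least 1 peak")
  expect_error(Spectrum(c(50, 50), c(1, 2)), "strictly ascending")
  expect_error(Spectrum(50, -1), ">= 0")
  expect_error(Spectrum(50, 1, rt = -0.1), "rt")
})

test_that("PyRun validates mode-dependent scan ranges and rt order", {
  s1 <- Spectrum(c(50, 91), c(10, 999), rt = 0.1)
  s2 <- Spectrum(c(700), c(5), rt = 0.2)
  expect_s4_class(PyRun(list(s1, s2), "pyrolysis"), "PyRun")
  expect_error(PyRun(list(s1, s2), "ega"), "scan range")  # 700 > 650
  expect_error(PyRun(list(s2, s1), "pyrolysis"), "non-decreasing")
})

test_that("mzML round-trip preserves scans, rts and peaks", {
  scansIn <- list(Spectrum(c(50, 91), c(1e5, 2e5), rt = 0.00),
                  Spectrum(c(44, 91, 120), c(3e4, 1e5, 7e4), rt = 0.01),
                  Spectrum(c(60), c(5e4), rt = 0.02))
  run <- PyRun(scansIn, "pyrolysis")
  f <- tempfile(fileext = ".mzML")
  writeMzML(run, f)
  back <- readMzML(f, "pyrolysis")
  expect_length(scans(back), 3)
  expect_equal(scanTimes(back), c(0.00, 0.01, 0.02), tolerance = 1e-9)
  for (k in 1:3) {
    expect_equal(mz(scans(back)[[k]]), mz(scansIn[[k]]), tolerance = 1e-9)
    expect_equal(intensity(scans(back)[[k]]), intensity(scansIn[[k]]),
                 tolerance = 1e-7)
  }
})

test_that("peaks outside the mode's scan range are dropped on load", {
  # file containing m/z 20 (below the scan floor of 29) and 860 (above the
  # pyrolysis ceiling of 850), written through mzR directly
  pks <- list(cbind(mz = c(20, 30, 91, 860), intensity = c(5, 1e5, 2e5, 7)))
  hdr <- data.frame(
    seqNum = 1L, acquisitionNum = 1L, msLevel = 1L, polarity = 1L,
    peaksCount = 4L, totIonCurrent = 3e5 + 12, retentionTime = 6,
    basePeakMZ = 91, basePeakIntensity = 2e5, collisionEnergy = 0,
    ionisationEnergy = 70, lowMZ = 20, highMZ = 860, precursorScanNum = 0L,
    precursorMZ = 0, precursorCharge = 0L, precursorIntensity = 0,
    mergedScan = 0L, mergedResultScanNum = 0L, mergedResultStartScanNum = 0L,
    mergedResultEndScanNum = 0L, injectionTime = 0,
    filterString = NA_character_, spectrumId = "scan=1", centroided = TRUE,
    ionMobilityDriftTime = NA_real_, isolationWindowTargetMZ = NA_real_,
    isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_, scanWindowLowerLimit = NA_real_,
    scanWindowUpperLimit = NA_real_)
  f <- tempfile(fileext = ".mzML")
  mzR::writeMSData(pks, f, header = hdr, outformat = "mzml")
  run <- readMzML(f, "pyrolysis")
  expect_equal(mz(scans(run)[[1]]), c(30, 91))
  expect_equal(scanTimes(run), 0.1)   # seconds converted to minutes
})

test_that("MSP parsing: identity, declared-count mismatch, round-trip", {
  f <- tempfile(fileext = ".msp")
  writeLines(c("Name: Toluene", "Num Peaks: 3", "91 999 65 120", "39 80", "",
               "Name: Phenol", "Class: phenols", "Num Peaks: 2",
               "94 999; 66 250", ""), f)
  lib <- readMSP(f)
  expect_length(lib, 2)
  expect_equal(names(lib), c("Toluene", "Phenol"))
  expect_equal(mz(lib$Phenol@spectrum), c(66, 94))
  expect_equal(lib$Phenol@classHint, "phenols")

  bad <- tempfile(fileext = ".msp")
  writeLines(c("Name: Styrene", "Num Peaks: 3", "104 999 78 300", ""), bad)
  expect_error(readMSP(bad), "Styrene")

  f2 <- tempfile(fileext = ".msp")
  writeMSP(lib, f2)
  back <- readMSP(f2)
  expect_equal(names(back), names(lib))
  for (nm in names(lib)) {
    expect_equal(mz(back[[nm]]@spectrum), mz(lib[[nm]]@spectrum))
    expect_equal(intensity(back[[nm]]@spectrum),
                 intensity(lib[[nm]]@spectrum))
  }
})

test_that("MGF round-trips spectra with titles and retention times", {
  sp <- list(A = Spectrum(c(50, 77), c(100, 50), rt = 1.5),
             B = Spectrum(c(41, 43, 57), c(999, 700, 400), rt = 2))
  f <- tempfile(fileext = ".mgf")
  writeMGF(sp, f)
  back <- readMGF(f)
  expect_equal(names(back), c("A", "B"))
  expect_equal(mz(back$A@spectrum), c(50, 77))
  expect_equal(back$A@spectrum@rt, 1.5, tolerance = 1e-9)
})

test_that("class library accepts the 12 classes, rejects others, dedups", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("compound,class", "Phenol,phenols", "Toluene,MAH",
               "Phenol,phenols"), f)
  cl <- readClassLibrary(f)
  expect_length(cl@entries, 2)          # exact duplicate collapsed
  expect_equal(classLookup(cl, "  PHENOL "), "phenols")  # normalized match
  expect_equal(classLookup(cl, "Naphthalene"), "unclassified")

  f2 <- tempfile(fileext = ".csv")
  writeLines(c("compound,class", "Cholesterol,lipids"), f2)
  expect_error(readClassLibrary(f2), "lipids")
  # an extended user-supplied class set is allowed
  cl2 <- readClassLibrary(f2, classes = c(somClasses(), "lipids"))
  expect_equal(classLookup(cl2, "Cholesterol"), "lipids")

  f3 <- tempfile(fileext = ".csv")
  writeLines(c("compound,class", "Phenol,phenols", "Phenol,MAH"), f3)
  expect_error(readClassLibrary(f3), "[Cc]onflict")

  f4 <- tempfile(fileext = ".csv")
  writeLines(c("name,class", "Phenol,phenols"), f4)
  expect_error(readClassLibrary(f4), "compound")
})

test_that("loaded synthetic mzML always satisfies the Spectrum invariants", {
  for (seed in 1:4) {
    g <- genRun(genCompoundSet(5, seed = seed), noiseSd = 2e3, seed = seed)
    f <- tempfile(fileext = ".mzML")
    writeMzML(g$run, f)
    back <- readMzML(f, "pyrolysis")
    rng <- scanRange("pyrolysis")
    for (s in scans(back)) {
      expect_true(all(diff(mz(s)) > 0))
      expect_true(all(intensity(s) >= 0))
      expect_true(all(mz(s) >= rng[1] & mz(s) <= rng[2]))
      expect_gte(length(mz(s)), 1)
    }
  }
})
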