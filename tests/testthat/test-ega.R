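test_that("the temperature program maps times correctly", {
  prog <- TemperatureProgram()
  expect_equal(timeToTemp(0.5, prog), 100)    # inside the 1 min hold
  expect_equal(timeToTemp(11, prog), 200)     # 100 + 10 * (11 - 1)
  expect_equal(timeToTemp(81, prog), 900)     # end of the ramp
  expect_equal(timeToTemp(95, prog), 900)     # capped
  expect_error(timeToTemp(-1, prog), ">= 0")
  # non-decreasing, piecewise linear, invertible within the ramp
  t <- seq(0, 90, by = 0.25)
  temps <- timeToTemp(t, prog)
  expect_true(all(diff(temps) >= 0))
  ramp <- t > 1 & temps < 900
  expect_equal(tempToTime(temps[ramp], prog), t[ramp], tolerance = 1e-12)
  expect_error(TemperatureProgram(startTemp = 500, endTemp = 400), "exceed")
})

test_that("class XICs sum the requested m/z bins and conserve the TIC", {
  run <- genEGARun(list(
    list(mz = 105, peakTemp = 450, width = 30, height = 1e6),
    list(mz = c(94, 107, 108), peakTemp = 380, width = 30, height = 6e5)))
  lignin <- egaCurve(run, channel = 105, smooth = 1)
  phen <- egaCurve(run, channel = c(94, 107, 108), smooth = 1)
  tic <- egaCurve(run, smooth = 1)
  # the m/z 105 trace is exactly the lignin component's profile
  expect_equal(which.max(intensity(lignin)),
               which.min(abs(curveTemps(lignin) - 450)))
  # XIC over all bins reproduces the TIC exactly, scan by scan
  allmz <- sort(unique(unlist(lapply(scans(run), function(s) round(mz(s))))))
  xicAll <- egaCurve(run, channel = allmz, smooth = 1)
  expect_equal(intensity(xicAll), intensity(tic))
  expect_equal(intensity(tic),
               intensity(lignin) + intensity(phen) +
                 intensity(egaCurve(run, channel = 40, smooth = 1)))
  expect_error(egaCurve(run, channel = numeric()), "non-empty")
})

test_that("peak temperatures are recovered within one scan bin", {
  prog <- TemperatureProgram()
  run <- genEGARun(list(list(mz = 105, peakTemp = 455, width = 25,
                             height = 1e6)), prog)
  tic <- egaCurve(run, prog)
  pt <- peakTemperatures(tic)
  binWidth <- 10 / 30            # 10 degC/min at a 2 s scan interval
  expect_equal(length(pt), 1)
  expect_lte(abs(pt[1] - 455), binWidth + 1e-9)

  # bimodal: both reported, larger first
  run2 <- genEGARun(list(list(mz = 91, peakTemp = 362, width = 18,
                              height = 6e5),
                         list(mz = 105, peakTemp = 436, width = 18,
                              height = 1e6)))
  pt2 <- peakTemperatures(egaCurve(run2, prog))
  expect_equal(length(pt2), 2)
  expect_lte(abs(pt2[1] - 436), binWidth + 1e-9)
  expect_lte(abs(pt2[2] - 362), binWidth + 1e-9)

  flat <- new("EGACurve", temps = seq(100, 900, 10),
              intensity = rep(3, 81), channel = numeric())
  expect_identical(peakTemperatures(flat), numeric())
})

test_that("high-temperature signal is flagged and attributed via CO2", {
  prog <- TemperatureProgram()
  # all signal below 600: no flag
  low <- genEGARun(list(list(mz = 105, peakTemp = 450, width = 25,
                             height = 1e6)), prog)
  ht <- highTempFlag(egaCurve(low, prog), egaCurve(low, prog, channel = 44))
  expect_false(ht$flag)
  expect_equal(ht$label, "none")

  # carbonate-like CO2 peak at 723: flagged, IC-consistent
  carb <- genEGARun(list(list(mz = 105, peakTemp = 430, width = 25,
                              height = 1e6),
                         list(mz = 44, peakTemp = 723, width = 20,
                              height = 5e5)), prog)
  ht2 <- highTempFlag(egaCurve(carb, prog), egaCurve(carb, prog, channel = 44))
  expect_true(ht2$flag)
  expect_equal(ht2$label, "IC-consistent")
  expect_gt(ht2$co2Share, 0.5)

  # CO2-poor high-temperature peak at 780: stable-OM-consistent
  stab <- genEGARun(list(list(mz = 105, peakTemp = 430, width = 25,
                              height = 1e6),
                         list(mz = c(78, 91), peakTemp = 780, width = 20,
                              height = 5e5)), prog)
  ht3 <- highTempFlag(egaCurve(stab, prog), egaCurve(stab, prog, channel = 44))
  expect_true(ht3$flag)
  expect_equal(ht3$label, "stable-OM-consistent")
})
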