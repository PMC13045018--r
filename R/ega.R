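# Evolved gas analysis: scan times are mapped onto the furnace temperature
# program, class-specific extracted-ion curves are built by summing the
# major m/z of the class's marker compounds, peak temperatures are read off
# the smoothed curve, and signal above the high-temperature cutoff
# (default 650 degC) is flagged as inorganic-carbon- or stable-OM-consistent
# depending on CO2 (m/z 44) dominance.

#' Map acquisition time to furnace temperature
#'
#' Temperature is `startTemp` during the initial hold, then rises linearly
#' at `rampRate` and is capped at `endTemp`. Non-decreasing and piecewise
#' linear in t.
#'
#' @param t time since run start, minutes (vectorized, >= 0).
#' @param prog a \linkS4class{TemperatureProgram}.
#' @return Temperature(s) in degC.
#' @examples
#' timeToTemp(c(0.5, 11, 81), TemperatureProgram())  # 100, 200, 900
#' @export
timeToTemp <- function(t, prog = TemperatureProgram()) {
  if (any(t < 0)) stop("t must be >= 0")
  pmin(prog@endTemp,
       ifelse(t <= prog@hold, prog@startTemp,
              prog@startTemp + prog@rampRate * (t - prog@hold)))
}

#' Map furnace temperature back to acquisition time
#'
#' Inverse of [timeToTemp()] within the ramp.
#'
#' @param temp temperature in degC, within `[startTemp, endTemp]`.
#' @param prog a \linkS4class{TemperatureProgram}.
#' @return Time in minutes at which the ramp reaches `temp` (the end of the
#'   hold for `startTemp`).
#' @export
tempToTime <- function(temp, prog = TemperatureProgram()) {
  if (any(temp < prog@startTemp | temp > prog@endTemp))
    stop("temp outside the program range")
  prog@hold + (temp - prog@startTemp) / prog@rampRate
}

#' Build an EGA curve (TIC or class XIC)
#'
#' Per scan, intensity is the summed intensity of the channel's unit-mass
#' bins (every bin for TIC); scan times are mapped to temperatures via
#' [timeToTemp()]. A centered moving average (default window 5 scans,
#' shrinking at the edges) smooths the coarse 2-second-scan curves;
#' `smooth = 1` disables it. The sum over all single-m/z XICs equals the
#' unsmoothed TIC exactly (per-scan ion-current conservation).
#'
#' @param run an EGA-mode \linkS4class{PyRun}.
#' @param prog a \linkS4class{TemperatureProgram}.
#' @param channel `"TIC"` or a numeric vector of m/z bins to sum (e.g.
#'   `c(94, 107, 108)` for the phenol class, `105` for lignin markers,
#'   `44` for CO2).
#' @param smooth moving-average window in scans (default 5).
#' @return An \linkS4class{EGACurve}.
#' @export
egaCurve <- function(run, prog = TemperatureProgram(), channel = "TIC",
                     smooth = 5) {
  if (runMode(run) != "ega") stop("egaCurve expects an EGA-mode run")
  tic <- identical(channel, "TIC")
  if (!tic) {
    channel <- as.numeric(channel)
    if (!length(channel)) stop("channel m/z list must be non-empty")
  }
  ints <- vapply(run@scans, function(s) {
    if (tic) sum(s@intensity)
    else sum(s@intensity[round(s@mz) %in% round(channel)])
  }, numeric(1))
  temps <- timeToTemp(scanTimes(run), prog)
  new("EGACurve", temps = temps, intensity = movingAverage(ints, smooth),
      channel = if (tic) numeric() else channel)
}

#' Peak temperatures of an EGA curve
#'
#' Local maxima with topographic prominence of at least `minProminence`
#' times the curve maximum, sorted by intensity descending -- the first
#' element is the global peak temperature. A flat curve has no peaks.
#'
#' @param curve an \linkS4class{EGACurve}.
#' @param minProminence minimum prominence as a fraction of the curve
#'   maximum (0 < p <= 1; default 0.1).
#' @return Numeric vector of peak temperatures (degC), intensity-sorted.
#' @export
peakTemperatures <- function(curve, minProminence = 0.1) {
  if (minProminence <= 0 || minProminence > 1)
    stop("minProminence must be in (0, 1]")
  y <- curve@intensity
  if (max(y) <= min(y)) return(numeric())
  idx <- localMaxima(y)
  if (!length(idx)) return(numeric())
  prom <- vapply(idx, function(i) prominence(y, i), numeric(1))
  idx <- idx[prom >= minProminence * max(y)]
  if (!length(idx)) return(numeric())
  idx <- idx[order(-y[idx])]
  curve@temps[idx]
}

# Topographic prominence of the local maximum at index i: height above the
# higher of the two key saddles (the lowest point between the peak and the
# nearest higher ground on each side; the trace end where no higher ground
# exists).
prominence <- function(y, i) {
  n <- length(y)
  left <- if (i > 1) y[1:(i - 1)] else numeric()
  right <- if (i < n) y[(i + 1):n] else numeric()
  saddle <- function(seg, rev) {
    if (!length(seg)) return(-Inf)
    if (rev) seg <- rev(seg)
    higher <- which(seg > y[i])
    if (length(higher)) min(seg[1:higher[1]]) else min(seg)
  }
  sl <- saddle(left, rev = TRUE)
  sr <- saddle(right, rev = FALSE)
  key <- max(sl, sr)
  if (!is.finite(key)) key <- min(y)
  y[i] - key
}

#' Flag high-temperature (inorganic / stable OM) signal
#'
#' Signal evolving above the cutoff (default 650 degC) can indicate
#' inorganic carbonates or highly thermally stable organic matter. The flag
#' fires when any reported peak temperature exceeds the cutoff. The region
#' above the cutoff is called CO2-dominated (inorganic-carbon-consistent)
#' when the CO2 (m/z 44) channel contributes more than `co2Dominance` of the
#' curve's summed intensity there; otherwise it is stable-OM-consistent.
#'
#' @param curve the \linkS4class{EGACurve} under test (typically TIC).
#' @param co2Curve the m/z 44 \linkS4class{EGACurve} from the same run.
#' @param cutoff temperature cutoff in degC (default 650).
#' @param co2Dominance CO2 share above which the region counts as
#'   CO2-dominated (default 0.5).
#' @param minProminence passed to [peakTemperatures()].
#' @return List with `flag` (any peak above cutoff), `peakTemps`,
#'   `fractionAbove` (share of total signal above cutoff), `co2Share`
#'   (CO2 share of the above-cutoff signal, `NA` if no signal there) and
#'   `label` (`"none"`, `"IC-consistent"` or `"stable-OM-consistent"`).
#' @export
highTempFlag <- function(curve, co2Curve, cutoff = 650, co2Dominance = 0.5,
                         minProminence = 0.1) {
  pt <- peakTemperatures(curve, minProminence)
  flag <- any(pt > cutoff)
  above <- curve@temps > cutoff
  fracAbove <- sum(curve@intensity[above]) / sum(curve@intensity)
  co2Share <- NA_real_
  if (any(above) && sum(curve@intensity[above]) > 0) {
    co2Above <- stats::approx(co2Curve@temps, co2Curve@intensity,
                              xout = curve@temps[above], rule = 2,
                              ties = mean)$y
    co2Share <- sum(co2Above) / sum(curve@intensity[above])
  }
  label <- if (!flag) "none"
  else if (!is.na(co2Share) && co2Share > co2Dominance) "IC-consistent"
  else "stable-OM-consistent"
  list(flag = flag, peakTemps = pt, fractionAbove = fracAbove,
       co2Share = co2Share, label = label)
}

#' Export an EGA curve as delimited text
#'
#' @param curve an \linkS4class{EGACurve}.
#' @param path output path (comma-separated: temp_C, intensity).
#' @return `path`, invisibly.
#' @export
writeEGACurve <- function(curve, path) {
  utils::write.csv(data.frame(temp_C = curve@temps,
                              intensity = curve@intensity),
                   path, row.names = FALSE)
  invisible(path)
}
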