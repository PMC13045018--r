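# Readers and writers: mzML (via mzR), MSP/MGF spectral libraries, and the
# delimited compound-class table. Retention times are normalized to minutes
# on load regardless of source units, because every chromatographic
# tolerance downstream (0.05 min RT window etc.) is expressed in minutes.

#' Read an mzML acquisition
#'
#' Loads all MS1 scans of an mzML file into a \linkS4class{PyRun}. Retention
#' times are converted from the mzML convention (seconds) to minutes. Peaks
#' outside the mode's scan range (m/z 29--850 for pyrolysis, 29--650 for
#' EGA; see [scanRange()]) are dropped. Profile-mode scans are centroided by
#' local-maximum picking, since all downstream arithmetic assumes stick
#' spectra.
#'
#' @param path path to an mzML file.
#' @param mode acquisition mode, `"pyrolysis"` (default) or `"ega"`.
#' @return A \linkS4class{PyRun}.
#' @seealso [writeMzML()]
#' @export
readMzML <- function(path, mode = c("pyrolysis", "ega")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("file not found: ", path)
  h <- tryCatch(mzR::openMSfile(path),
                error = function(e) stop("malformed mzML '", path, "': ",
                                         conditionMessage(e)))
  on.exit(mzR::close(h), add = TRUE)
  hdr <- mzR::header(h)
  ms1 <- which(hdr$msLevel == 1L)
  if (!length(ms1)) stop("empty run: no MS1 scans in ", path)
  rng <- scanRange(mode)
  scans <- vector("list", length(ms1))
  for (k in seq_along(ms1)) {
    i <- ms1[k]
    p <- tryCatch(mzR::peaks(h, i),
                  error = function(e) stop("malformed mzML '", path,
                                           "': bad scan ", i, ": ",
                                           conditionMessage(e)))
    m <- p[, 1]; int <- p[, 2]
    if (isFALSE(hdr$centroided[i])) {
      cp <- centroidProfile(m, int); m <- cp$mz; int <- cp$intensity
    }
    keep <- m >= rng[1] & m <= rng[2] & !is.na(int)
    m <- m[keep]; int <- int[keep]
    if (!length(m)) { scans[[k]] <- NULL; next }
    scans[[k]] <- Spectrum(m, int, rt = hdr$retentionTime[i] / 60,
                           metadata = list(scan = as.character(i)))
  }
  drop <- vapply(scans, is.null, logical(1))
  if (all(drop)) stop("empty run: no in-range MS1 peaks in ", path)
  if (any(drop))
    warning(sum(drop), " scan(s) had no peaks inside the ", mode,
            " scan range and were dropped")
  PyRun(scans[!drop], mode = mode)
}

# Centroid a profile trace by local-maximum picking.
centroidProfile <- function(m, int) {
  idx <- localMaxima(int)
  if (!length(idx)) idx <- which.max(int)
  list(mz = m[idx], intensity = int[idx])
}

#' Write a run to mzML
#'
#' @param run a \linkS4class{PyRun}.
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [readMzML()]
#' @export
writeMzML <- function(run, path) {
  sc <- run@scans
  n <- length(sc)
  if (!n) stop("cannot write an empty run")
  pks <- lapply(sc, function(s) cbind(mz = s@mz, intensity = s@intensity))
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = 1L,
    polarity = 1L,
    peaksCount = vapply(pks, nrow, integer(1)),
    totIonCurrent = vapply(sc, function(s) sum(s@intensity), numeric(1)),
    retentionTime = vapply(sc, function(s) s@rt, numeric(1)) * 60,
    basePeakMZ = vapply(sc, function(s) s@mz[which.max(s@intensity)],
                        numeric(1)),
    basePeakIntensity = vapply(sc, function(s) max(s@intensity), numeric(1)),
    collisionEnergy = 0, ionisationEnergy = 70,
    lowMZ = vapply(sc, function(s) min(s@mz), numeric(1)),
    highMZ = vapply(sc, function(s) max(s@mz), numeric(1)),
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = paste0("scan=", seq_len(n)), centroided = TRUE,
    ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_, isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_,
    scanWindowLowerLimit = NA_real_, scanWindowUpperLimit = NA_real_,
    stringsAsFactors = FALSE)
  mzR::writeMSData(pks, path, header = hdr, outformat = "mzml")
  invisible(path)
}

## ----------------------------------------------------------------- MSP/MGF

#' Read an MSP spectral library
#'
#' Parses NIST-style MSP text: records start at `Name:`, declare
#' `Num Peaks:`, and list m/z--intensity pairs (whitespace or semicolon
#' separated, several pairs per line allowed). An optional `Class:` field is
#' kept as a class hint. A record whose listed peak count differs from its
#' declaration is an error naming the record.
#'
#' @param path path to an MSP file.
#' @return List of \linkS4class{LibraryEntry}, named by compound.
#' @seealso [writeMSP()], [readMGF()]
#' @export
readMSP <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^name:", lines, ignore.case = TRUE)
  if (!length(starts)) stop("no 'Name:' records in ", path)
  ends <- c(starts[-1] - 1L, length(lines))
  entries <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    rec <- lines[starts[k]:ends[k]]
    nm <- trimws(sub("^name:\\s*", "", rec[1], ignore.case = TRUE))
    npLine <- grep("^num\\s*peaks:", rec, ignore.case = TRUE)
    if (!length(npLine)) stop("record '", nm, "' has no 'Num Peaks:' line")
    np <- as.integer(trimws(sub("^num\\s*peaks:\\s*", "", rec[npLine[1]],
                                ignore.case = TRUE)))
    clLine <- grep("^class:", rec, ignore.case = TRUE)
    classHint <- if (length(clLine))
      trimws(sub("^class:\\s*", "", rec[clLine[1]], ignore.case = TRUE))
    else NA_character_
    peakLines <- rec[seq(npLine[1] + 1L, length(rec))]
    toks <- unlist(strsplit(paste(peakLines, collapse = " "),
                            "[;,[:space:]]+"))
    toks <- toks[nzchar(toks)]
    vals <- suppressWarnings(as.numeric(toks))
    vals <- vals[!is.na(vals)]
    if (length(vals) %% 2 != 0 || length(vals) / 2 != np)
      stop("record '", nm, "': declared Num Peaks ", np, " but found ",
           floor(length(vals) / 2))
    m <- vals[seq(1, length(vals), 2)]
    i <- vals[seq(2, length(vals), 2)]
    entries[[k]] <- LibraryEntry(nm, Spectrum(m, i), classHint)
  }
  names(entries) <- vapply(entries, function(e) e@name, character(1))
  entries
}

#' Write an MSP spectral library
#'
#' @param entries list of \linkS4class{LibraryEntry}.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeMSP <- function(entries, path) {
  con <- file(path, "w"); on.exit(close(con), add = TRUE)
  for (e in entries) {
    s <- e@spectrum
    writeLines(paste0("Name: ", e@name), con)
    if (!is.na(e@classHint)) writeLines(paste0("Class: ", e@classHint), con)
    writeLines(paste0("Num Peaks: ", length(s@mz)), con)
    writeLines(paste(s@mz, s@intensity), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read an MGF spectral file
#'
#' Sibling reader to [readMSP()] for MGF (`BEGIN IONS`/`END IONS`) blocks;
#' `TITLE` becomes the entry name, `RTINSECONDS` the retention time.
#'
#' @param path path to an MGF file.
#' @return List of \linkS4class{LibraryEntry}, named by title.
#' @export
readMGF <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^BEGIN IONS", lines)
  ends <- grep("^END IONS", lines)
  if (length(starts) != length(ends) || !length(starts))
    stop("malformed MGF: unbalanced BEGIN/END IONS in ", path)
  entries <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    rec <- lines[(starts[k] + 1L):(ends[k] - 1L)]
    kv <- grepl("=", rec, fixed = TRUE)
    title <- sub("^TITLE=", "", grep("^TITLE=", rec, value = TRUE)[1])
    if (is.na(title)) title <- paste0("spectrum_", k)
    rtl <- grep("^RTINSECONDS=", rec, value = TRUE)
    rt <- if (length(rtl)) as.numeric(sub("^RTINSECONDS=", "", rtl[1])) / 60 else 0
    pk <- rec[!kv]
    pk <- pk[nzchar(trimws(pk))]
    vals <- as.numeric(unlist(strsplit(trimws(pk), "\\s+")))
    if (length(vals) < 2) stop("MGF record '", title, "' has no peaks")
    m <- vals[seq(1, length(vals), 2)]
    i <- vals[seq(2, length(vals), 2)]
    entries[[k]] <- LibraryEntry(title, Spectrum(m, i, rt = max(rt, 0)))
  }
  names(entries) <- vapply(entries, function(e) e@name, character(1))
  entries
}

#' Write spectra to MGF
#'
#' @param entries list of \linkS4class{LibraryEntry} (or named list of
#'   \linkS4class{Spectrum}).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeMGF <- function(entries, path) {
  con <- file(path, "w"); on.exit(close(con), add = TRUE)
  nms <- names(entries)
  for (k in seq_along(entries)) {
    e <- entries[[k]]
    if (is(e, "LibraryEntry")) { s <- e@spectrum; nm <- e@name }
    else { s <- e; nm <- if (!is.null(nms)) nms[k] else paste0("spectrum_", k) }
    writeLines(c("BEGIN IONS", paste0("TITLE=", nm),
                 paste0("RTINSECONDS=", s@rt * 60), "CHARGE=1+"), con)
    writeLines(paste(s@mz, s@intensity), con)
    writeLines(c("END IONS", ""), con)
  }
  invisible(path)
}

## ------------------------------------------------------------ class library

#' Read the compound-class table
#'
#' Reads a delimited table (comma or tab, autodetected; header required)
#' with columns `compound` and `class` mapping compound names to compound
#' classes. Compound keys are matched case-insensitively with whitespace
#' normalized. Class names must belong to the permitted set -- by default
#' the 12 classes of [somClasses()]; pass an extended `classes` vector to
#' accept additional classes. Exact duplicates are deduplicated; a compound
#' listed with two different classes is an error naming the conflicts.
#'
#' @param path path to the delimited table.
#' @param classes permitted class names (default [somClasses()]).
#' @return A \linkS4class{ClassLibrary}.
#' @export
readClassLibrary <- function(path, classes = somClasses()) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE, quote = "\"",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "")
  names(df) <- tolower(trimws(names(df)))
  if (!all(c("compound", "class") %in% names(df)))
    stop("class table must have columns 'compound' and 'class'; found: ",
         paste(names(df), collapse = ", "))
  ClassLibrary(df$compound, df$class, classes = classes)
}

#' Construct a ClassLibrary
#'
#' @param compounds compound names.
#' @param compoundClasses class per compound (same length as `compounds`).
#' @param classes permitted class names (default [somClasses()]).
#' @return A \linkS4class{ClassLibrary}.
#' @export
ClassLibrary <- function(compounds, compoundClasses, classes = somClasses()) {
  key <- normalizeCompound(compounds)
  cls <- trimws(compoundClasses)
  bad <- setdiff(unique(cls), classes)
  if (length(bad))
    stop("class name(s) not in the permitted class set: ",
         paste(bad, collapse = ", "),
         ". Pass an extended 'classes' vector to accept them.")
  # dedupe identical rows; conflicting duplicates are an error
  df <- unique(data.frame(key = key, cls = cls, stringsAsFactors = FALSE))
  dup <- df$key[duplicated(df$key)]
  if (length(dup))
    stop("conflicting classes for compound(s): ",
         paste(unique(dup), collapse = ", "))
  new("ClassLibrary", entries = stats::setNames(df$cls, df$key),
      classes = classes)
}

#' Look up the class of a compound
#'
#' @param library a \linkS4class{ClassLibrary}.
#' @param compound compound name(s); matching is case-insensitive and
#'   whitespace-normalized.
#' @return Character vector of class names, `"unclassified"` where absent.
#' @export
classLookup <- function(library, compound) {
  out <- unname(library@entries[normalizeCompound(compound)])
  out[is.na(out)] <- "unclassified"
  out
}
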