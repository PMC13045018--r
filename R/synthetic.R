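# Ground-truthed synthetic data: EI spectra organized in structural
# families (within-family cosine high, cross-family low), Gaussian elution
# chromatograms with controlled co-elution and noise, EGA thermograms with
# planted peak temperatures, and multi-ecosystem sample designs with a
# shared core, ecosystem-specific tails and a wetland-exclusive compound
# set. All generators are deterministic under a fixed seed and leave the
# caller's RNG state untouched.

# Base fragment set of a structural family: derived from the family tag
# alone, so every member of the family sees the same base spectrum.
familyBase <- function(family) {
  withSeed(7151 + 97L * as.integer(family), {
    nFrag <- sample(12:20, 1)
    mzs <- sort(sample(30:300, nFrag))
    ints <- stats::runif(nFrag)^2 * 950 + 40
    list(mz = mzs, intensity = ints / max(ints) * 999)
  })
}

#' Generate one synthetic compound
#'
#' Members of the same structural family share at least 60% of their
#' fragment m/z with log-normally perturbed intensities, so within-family
#' cosine typically exceeds 0.7 while compounds from different families
#' (independent random fragment sets) rarely exceed 0.5.
#'
#' @param seed integer seed; the same seed always gives the same compound.
#' @param family structural-family tag (integer); controls fragment sharing.
#' @param compoundClass one of [somClasses()] (default: drawn from the 12).
#' @param name compound name (default derived from seed and family).
#' @return List with `name`, `spectrum` (\linkS4class{Spectrum}, base peak
#'   999, 5--40 fragments), `rt` (minutes), `height` (counts),
#'   `compoundClass` and `family`.
#' @export
genCompound <- function(seed, family = 1L, compoundClass = NULL,
                        name = NULL) {
  base <- familyBase(family)
  withSeed(seed, {
    n <- length(base$mz)
    nKeep <- sample(ceiling(0.75 * n):n, 1)          # >= 60% shared
    # low-intensity fragments are the ones that vary between family members;
    # the diagnostic high ones are retained, keeping within-family cosine high
    keep <- sort(sample(n, nKeep, prob = base$intensity + 10))
    mzs <- base$mz[keep]
    ints <- base$intensity[keep] * exp(stats::rnorm(nKeep, 0, 0.2))
    nPriv <- sample(0:3, 1)
    if (nPriv) {
      pm <- sample(setdiff(30:300, mzs), nPriv)
      mzs <- c(mzs, pm)
      ints <- c(ints, stats::runif(nPriv) * 150 + 10)
    }
    ints <- ints / max(ints) * 999
    if (is.null(compoundClass)) compoundClass <- sample(somClasses(), 1)
    if (is.null(name)) name <- sprintf("cmpd_f%d_s%d", family, seed)
    list(name = name,
         spectrum = Spectrum(mzs, ints),
         rt = stats::runif(1, 0.3, 2.7),
         height = stats::rlnorm(1, log(1e6), 0.5),
         compoundClass = compoundClass,
         family = family)
  })
}

#' Generate a set of synthetic compounds
#'
#' @param n number of compounds.
#' @param nFamilies number of structural families, assigned round-robin.
#' @param seed integer seed (compound k uses `seed * 1000 + k`).
#' @param classes class pool to draw from (default [somClasses()]); a named
#'   numeric vector is interpreted as class sampling weights. Each structural
#'   family is assigned one class (structurally related pyrolysates belong to
#'   the same class), and compounds inherit their family's class.
#' @return List of compounds (see [genCompound()]) with distinct names and
#'   retention times spread over the run.
#' @export
genCompoundSet <- function(n, nFamilies = max(1, round(n / 4)), seed = 1,
                           classes = somClasses()) {
  w <- NULL
  if (!is.null(names(classes))) { w <- as.numeric(classes); classes <- names(classes) }
  famClass <- withSeed(seed, sample(classes, nFamilies, replace = TRUE,
                                    prob = w))
  fam <- ((seq_len(n) - 1L) %% nFamilies) + 1L
  cmp <- lapply(seq_len(n), function(k)
    genCompound(seed * 1000 + k, family = fam[k],
                compoundClass = famClass[fam[k]]))
  # jittered rt grid with guaranteed >= 0.08 min spacing: baseline compounds
  # are chromatographically resolvable, so co-elution stress is controlled
  # explicitly through genRun()'s coElutePairs rather than by accident
  rts <- withSeed(seed + 1,
                  0.3 + 0.12 * (seq_len(n) - 1) + stats::runif(n, 0, 0.04))
  for (k in seq_len(n)) cmp[[k]]$rt <- rts[k]
  cmp
}

#' Generate a synthetic pyrolysis run with known ground truth
#'
#' Each compound contributes a Gaussian elution profile (sd `peakWidth`,
#' default 0.02 min -- narrow enough that the standard 0.05 min RT tolerance
#' is genuinely stressed) times its fragment spectrum. `coElutePairs`
#' consecutive compound pairs are forced to apex separations drawn from
#' 0.02--0.05 min. Additive Gaussian noise of sd `noiseSd` is applied to
#' every populated m/z bin and clipped at zero.
#'
#' @param compounds list of compounds from [genCompound()] /
#'   [genCompoundSet()].
#' @param noiseSd additive noise sd in counts (default 0).
#' @param coElutePairs number of forced co-eluting pairs (default 0).
#' @param seed integer seed.
#' @param scanInterval scan spacing in minutes (default 0.005, i.e. 0.3 s).
#' @param peakWidth Gaussian elution sd in minutes (default 0.02).
#' @return List with `run` (a pyrolysis \linkS4class{PyRun}), `truth`
#'   (`data.frame`: name, rt, height, compoundClass, family, basePeak) and
#'   `compounds` (the rt-adjusted compound list).
#' @export
genRun <- function(compounds, noiseSd = 0, coElutePairs = 0, seed = 1,
                   scanInterval = 0.005, peakWidth = 0.02) {
  withSeed(seed, {
    n <- length(compounds)
    if (coElutePairs > 0) {
      if (2 * coElutePairs > n) stop("not enough compounds for the requested pairs")
      pick <- seq_len(2 * coElutePairs)
      for (p in seq_len(coElutePairs)) {
        a <- pick[2 * p - 1]; b <- pick[2 * p]
        compounds[[b]]$rt <- compounds[[a]]$rt + stats::runif(1, 0.02, 0.05)
      }
    }
    rts <- vapply(compounds, `[[`, numeric(1), "rt")
    grid <- seq(0, max(rts) + 0.15, by = scanInterval)
    bins <- sort(unique(unlist(lapply(compounds, function(cp)
      round(cp$spectrum@mz)))))
    M <- matrix(0, length(grid), length(bins),
                dimnames = list(NULL, as.character(bins)))
    for (cp in compounds) {
      prof <- cp$height * exp(-(grid - cp$rt)^2 / (2 * peakWidth^2))
      b <- as.character(round(cp$spectrum@mz))
      M[, b] <- M[, b] + outer(prof, cp$spectrum@intensity / 999)
    }
    if (noiseSd > 0)
      M <- pmax(M + matrix(stats::rnorm(length(M), 0, noiseSd),
                           nrow(M)), 0)
    scans <- lapply(seq_along(grid), function(i) {
      keep <- M[i, ] > 1e-9
      if (!any(keep))
        return(Spectrum(40, 0, rt = grid[i]))
      Spectrum(bins[keep], M[i, keep], rt = grid[i])
    })
    truth <- data.frame(
      name = vapply(compounds, `[[`, character(1), "name"),
      rt = rts <- vapply(compounds, `[[`, numeric(1), "rt"),
      height = vapply(compounds, `[[`, numeric(1), "height"),
      compoundClass = vapply(compounds, `[[`, character(1), "compoundClass"),
      family = vapply(compounds, function(cp) as.integer(cp$family),
                      integer(1)),
      basePeak = vapply(compounds, function(cp)
        round(cp$spectrum@mz[which.max(cp$spectrum@intensity)]), numeric(1)),
      stringsAsFactors = FALSE)
    list(run = PyRun(scans, mode = "pyrolysis",
                     scanInterval = scanInterval * 60),
         truth = truth, compounds = compounds)
  })
}

#' Generate a synthetic EGA run with planted thermal peaks
#'
#' Each component evolves a Gaussian-in-temperature profile over its m/z
#' channel, sampled on the program's time grid at the EGA scan interval
#' (default 2 s).
#'
#' @param components list of lists with `mz` (numeric m/z bins), `peakTemp`
#'   (degC), `width` (Gaussian sd in degC) and `height` (counts).
#' @param prog a \linkS4class{TemperatureProgram}.
#' @param noiseSd additive noise sd (default 0).
#' @param seed integer seed.
#' @param scanInterval scan spacing in minutes (default 1/30, i.e. 2 s).
#' @return An EGA-mode \linkS4class{PyRun}.
#' @export
genEGARun <- function(components, prog = TemperatureProgram(), noiseSd = 0,
                      seed = 1, scanInterval = 1 / 30) {
  withSeed(seed, {
    tEnd <- tempToTime(prog@endTemp, prog)
    grid <- seq(0, tEnd, by = scanInterval)
    temps <- timeToTemp(grid, prog)
    bins <- sort(unique(unlist(lapply(components, `[[`, "mz"))))
    M <- matrix(0, length(grid), length(bins),
                dimnames = list(NULL, as.character(bins)))
    for (cp in components) {
      prof <- cp$height * exp(-(temps - cp$peakTemp)^2 / (2 * cp$width^2))
      b <- as.character(cp$mz)
      M[, b] <- M[, b] + prof / length(cp$mz)
    }
    if (noiseSd > 0)
      M <- pmax(M + matrix(stats::rnorm(length(M), 0, noiseSd), nrow(M)), 0)
    scans <- lapply(seq_along(grid), function(i) {
      keep <- M[i, ] > 1e-9
      if (!any(keep)) return(Spectrum(40, 0, rt = grid[i]))
      Spectrum(bins[keep], M[i, keep], rt = grid[i])
    })
    PyRun(scans, mode = "ega", scanInterval = scanInterval * 60)
  })
}

#' Build a reference library and class library from synthetic compounds
#'
#' @param compounds list from [genCompoundSet()].
#' @return List with `library` (list of \linkS4class{LibraryEntry}) and
#'   `classes` (a \linkS4class{ClassLibrary}).
#' @export
genLibrary <- function(compounds) {
  lib <- lapply(compounds, function(cp)
    LibraryEntry(cp$name, cp$spectrum, cp$compoundClass))
  names(lib) <- vapply(lib, function(e) e@name, character(1))
  cl <- ClassLibrary(vapply(compounds, `[[`, character(1), "name"),
                     vapply(compounds, `[[`, character(1), "compoundClass"))
  list(library = lib, classes = cl)
}

#' Generate a multi-ecosystem sample design with known ground truth
#'
#' A compound pool with a globally shared core (`sharedFraction` of the
#' pool), ecosystem-specific tails, and a wetland-exclusive set present only
#' in the first two (wetland) ecosystems. Per-sample abundances are
#' log-normal (sd 1 on the log scale), giving realistic rank-abundance
#' curves.
#'
#' @param ecosystems number of ecosystems (default 5; >= 2 when
#'   `wetlandExclusive > 0`).
#' @param samplesPer replicate samples per ecosystem (default 3).
#' @param sharedFraction fraction of the pool present everywhere
#'   (0 to 1; default 0.3).
#' @param wetlandExclusive number of compounds present only in the two
#'   wetland ecosystems (default 24).
#' @param nCompounds total pool size (default 120).
#' @param seed integer seed.
#' @return List with `features` (named list: sample id -> list of
#'   \linkS4class{Feature}), `groups` (named character: sample -> ecosystem),
#'   `compounds`, `library`/`classes` (as [genLibrary()]), and `truth`
#'   (presence matrix compounds x ecosystems plus the wetland-exclusive
#'   compound names and ecosystem labels).
#' @export
genDesign <- function(ecosystems = 5, samplesPer = 3, sharedFraction = 0.3,
                      wetlandExclusive = 24, nCompounds = 120, seed = 1) {
  if (sharedFraction < 0 || sharedFraction > 1)
    stop("sharedFraction must be in [0, 1]")
  if (wetlandExclusive > 0 && ecosystems < 2)
    stop("wetland-exclusive compounds need at least 2 ecosystems")
  ecoNames <- if (ecosystems == 5)
    c("vernal_pool", "wet_prairie", "forest", "grassland", "tropical")
  else paste0("eco", seq_len(ecosystems))
  compounds <- genCompoundSet(nCompounds,
                              nFamilies = max(1, round(nCompounds / 5)),
                              seed = seed)
  withSeed(seed + 17, {
    nShared <- round(sharedFraction * nCompounds)
    idx <- seq_len(nCompounds)
    sharedIdx <- idx[seq_len(nShared)]
    rest <- setdiff(idx, sharedIdx)
    if (wetlandExclusive > length(rest))
      stop("pool too small for the requested wetland-exclusive set")
    wetIdx <- rest[seq_len(wetlandExclusive)]
    tailIdx <- setdiff(rest, wetIdx)
    presence <- matrix(FALSE, nCompounds, ecosystems,
                       dimnames = list(
                         vapply(compounds, `[[`, character(1), "name"),
                         ecoNames))
    presence[sharedIdx, ] <- TRUE
    if (wetlandExclusive > 0) presence[wetIdx, 1:2] <- TRUE
    if (length(tailIdx)) {
      ecoOf <- rep(seq_len(ecosystems), length.out = length(tailIdx))
      presence[cbind(tailIdx, ecoOf)] <- TRUE
    }
    features <- list(); groups <- character()
    for (e in seq_len(ecosystems)) for (r in seq_len(samplesPer)) {
      sid <- sprintf("%s_r%d", ecoNames[e], r)
      groups[sid] <- ecoNames[e]
      present <- which(presence[, e])
      features[[sid]] <- lapply(present, function(k) {
        cp <- compounds[[k]]
        h <- stats::rlnorm(1, log(cp$height), 1)
        Feature(cp$rt, cp$spectrum, height = h,
                area = h * 0.02 * sqrt(2 * pi), sampleId = sid)
      })
    }
    libs <- genLibrary(compounds)
    list(features = features, groups = groups, compounds = compounds,
         library = libs$library, classes = libs$classes,
         truth = list(presence = presence,
                      wetlandExclusive = rownames(presence)[wetIdx],
                      ecosystems = ecoNames))
  })
}
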