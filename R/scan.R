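# Workflow orchestration: run the Monte Carlo forward chain over the
# wavelength grid once, cache per-wavelength summaries, then scan
# wavelength sets (consecutive bands, evenly spread sets, photon-budget
# sweeps) and rank them by the uncertainty of brain
# cytochrome-c-oxidase recovery.

#' Run the forward chain over a wavelength grid
#'
#' Simulates one Monte Carlo run per wavelength of the model grid and
#' caches everything the wavelength scans need: the relative detected
#' signal, the clipped-DTOF moment shape, the two-layer sensitivity matrix
#' X and the "unit" absorption-change uncertainty (the uncertainty at
#' Ntot = 1, which scales exactly as 1/sqrt(Ntot) because the moment
#' covariance Z is proportional to 1/Ntot).
#'
#' @param model a [TissueModel-class].
#' @param geometry a [Geometry-class].
#' @param nPhotons photon packets per wavelength.
#' @param seed master seed; each wavelength uses `seed + index - 1`.
#' @param clipFraction clipping threshold for the moment window (see
#'   [clipDtof()]).
#' @return a forward cache (class `trnirsForwardCache`): a list with one
#'   entry per wavelength plus metadata.  Caches are plain lists and can
#'   be stored with `saveRDS()` for reuse across scans.
#' @export
runForwardGrid <- function(model, geometry = defaultGeometry(),
                           nPhotons = 1e6, seed = 1,
                           clipFraction = 0.01) {
  wl <- model@wavelengths
  entries <- vector("list", length(wl))
  for (i in seq_along(wl)) {
    res <- mcSimulate(model, wl[i], geometry, nPhotons = nPhotons,
                      seed = seed + i - 1)
    dtof <- simDtof(res)
    win <- .smoothedClipWindow(dtof@counts, clipFraction)
    m <- dtofMoments(new("DTOF", wavelength = dtof@wavelength,
                         times = dtof@times[win[1]:win[2]],
                         counts = dtof@counts[win[1]:win[2]],
                         channelWidth = dtof@channelWidth))
    sens <- sensitivityFactors(res)
    X <- twoLayerX(sens)
    mUnit <- m
    mUnit$Ntot <- 1
    zUnit <- covarianceZ(mUnit)
    sigmaUnit <- sigmaDmua(X, zUnit)$sigma
    entries[[i]] <- list(wavelength = wl[i],
                         signal = sum(dtof@counts) / res@nLaunched,
                         nDetected = nrow(res@photons),
                         moments = m, X = X, Xfull = sens@factors,
                         sigmaUnit = sigmaUnit,
                         counts = dtof@counts)
    rm(res)
  }
  structure(list(entries = entries, wavelengths = wl,
                 nPhotons = nPhotons, seed = seed,
                 clipFraction = clipFraction,
                 convention = model@convention,
                 geometry = geometry),
            class = "trnirsForwardCache")
}

#' @export
print.trnirsForwardCache <- function(x, ...) {
  cat(sprintf("trnirs forward cache: %d wavelengths %.1f-%.1f nm, %.3g photons/wavelength, seed %d\n",
              length(x$wavelengths), min(x$wavelengths),
              max(x$wavelengths), x$nPhotons, as.integer(x$seed)))
  invisible(x)
}

# Interpolate the cached per-wavelength curves onto an arbitrary grid.
# sigmaUnit is interpolated with a cubic spline through the simulated
# nodes (the convention for filling in non-simulated wavelengths); the
# relative signal curve is splined the same way.
.cacheCurves <- function(cache, wavelengths) {
  wl <- cache$wavelengths
  sigU <- t(vapply(cache$entries, function(e) e$sigmaUnit, numeric(2)))
  sig <- vapply(cache$entries, function(e) e$signal, numeric(1))
  onGrid <- all(vapply(wavelengths,
                       function(w) any(abs(wl - w) < 1e-6), logical(1)))
  if (onGrid) {
    idx <- vapply(wavelengths, function(w) which.min(abs(wl - w)),
                  integer(1))
    list(sigmaUnit = sigU[idx, , drop = FALSE], signal = sig[idx])
  } else {
    su <- vapply(seq_len(ncol(sigU)), function(j)
      interpolateCurve(wl, sigU[, j], wavelengths, method = "spline"),
      numeric(length(wavelengths)))
    su <- matrix(su, ncol = ncol(sigU), dimnames = list(NULL, colnames(sigU)))
    s <- interpolateCurve(wl, sig, wavelengths, method = "spline")
    list(sigmaUnit = pmax(su, .Machine$double.eps),
         signal = pmax(s, .Machine$double.eps))
  }
}

# Absorption-change uncertainty for one analysed wavelength set under the
# photon budget.  The budget can be normalised over the full simulated
# grid ("grid": Ntot(lambda) = budget * r s / sum_grid(r s), so a window
# keeps only its share of the grid-wide 1.5e6 photons and bands with poor
# detector response are penalised) or over the analysed set itself
# ("set": every analysed band receives the full budget).
.setSigma <- function(cache, wavelengths, responsivity = NULL,
                      budget = 1.5e6, normalize = c("grid", "set")) {
  normalize <- match.arg(normalize)
  cur <- .cacheCurves(cache, wavelengths)
  r <- if (is.null(responsivity)) rep(1, length(wavelengths))
       else spectrumValues(responsivity, wavelengths)
  if (any(r < 0)) stop("responsivity must be non-negative")
  share <- r * cur$signal
  if (sum(share) <= 0) stop("zero total signal over the wavelength set")
  denom <- if (normalize == "set") {
    sum(share)
  } else {
    grid <- .cacheCurves(cache, cache$wavelengths)
    rg <- if (is.null(responsivity)) rep(1, length(cache$wavelengths))
          else spectrumValues(responsivity, cache$wavelengths)
    sum(rg * grid$signal)
  }
  ntot <- budget * share / denom
  sigma <- cur$sigmaUnit / sqrt(ntot)
  list(sigma = sigma, ntot = ntot)
}

.bandRows <- function(cache, wavelengths, spectra, responsivity, budget,
                      label, normalize = "grid") {
  s <- .setSigma(cache, wavelengths, responsivity, budget, normalize)
  dc <- sigmaDC(s$sigma, wavelengths, spectra)
  dc$band_start_nm <- min(wavelengths)
  dc$band_end_nm <- max(wavelengths)
  dc$n_wavelengths <- length(wavelengths)
  dc$responsivity <- !is.null(responsivity)
  dc$budget <- budget
  dc$label <- label
  dc
}

.bestBand <- function(rows, layer = "brain", chromophore = "oxCCO") {
  sel <- rows[rows$layer == layer & rows$chromophore == chromophore, ]
  sel[which.min(sel$sigma_uM), ]
}

#' Scan bands of consecutive wavelengths
#'
#' Slides a window of `nWindow` consecutive grid wavelengths (16 channels
#' of the 12.5 nm grid by default) across the cached grid.  Each window is
#' renormalised to the photon budget (with or without the detector
#' responsivity), the per-wavelength absorption-change uncertainties are
#' evaluated, and the Beer-Lambert propagation yields the per-chromophore
#' concentration uncertainties.  The band minimising the brain
#' cytochrome-c-oxidase uncertainty is reported as the optimum.
#'
#' @param cache forward cache from [runForwardGrid()].
#' @param spectra chromophore spectra for the Beer-Lambert unmixing step;
#'   defaults to the bundled tables in the natural-log convention (the
#'   convention consistent with attenuation changes defined through ln).
#' @param responsivity `NULL` (uniform detector) or a responsivity
#'   [SpectralCurve-class].
#' @param budget total photon budget (see `normalize`).
#' @param nWindow window length in grid channels.
#' @param normalize photon-budget normalisation: `"grid"` (default)
#'   distributes the budget over the full simulated grid so each analysed
#'   band keeps only its share of the detected counts (a detector with
#'   poor long-wavelength response therefore starves red bands); `"set"`
#'   gives every analysed band the full budget.
#' @return data.frame of class `trnirsScan` with one row per (band, layer,
#'   chromophore); the optimal band row is attached as attribute `best`.
#' @export
scanConsecutive16 <- function(cache, spectra = NULL, responsivity = NULL,
                              budget = 1.5e6, nWindow = 16,
                              normalize = c("grid", "set")) {
  normalize <- match.arg(normalize)
  if (is.null(spectra)) spectra <- nirsSpectra("natural")
  wl <- cache$wavelengths
  if (nWindow > length(wl)) stop("window exceeds the cached grid")
  starts <- seq_len(length(wl) - nWindow + 1)
  rows <- do.call(rbind, lapply(starts, function(i) {
    w <- wl[i:(i + nWindow - 1)]
    .bandRows(cache, w, spectra, responsivity, budget,
              label = sprintf("%.1f-%.1f nm", min(w), max(w)),
              normalize = normalize)
  }))
  class(rows) <- c("trnirsScan", class(rows))
  attr(rows, "best") <- .bestBand(rows)
  rows
}

#' Scan evenly spread wavelength sets of varying size
#'
#' Evaluates sets of `counts` wavelengths spread evenly over the cached
#' span.  Uncertainties at wavelengths that were not simulated are filled
#' in by natural-cubic-spline interpolation of the per-wavelength
#' absorption-change uncertainty curve through the simulated nodes.
#'
#' @inheritParams scanConsecutive16
#' @param counts set sizes to evaluate.
#' @return data.frame of class `trnirsScan` with one row per (count,
#'   layer, chromophore); attribute `best` holds the optimum for brain
#'   cytochrome-c-oxidase.
#' @export
scanEvenSpread <- function(cache, spectra = NULL,
                           counts = c(4, 8, 12, 16, 20, 25, 32),
                           responsivity = NULL, budget = 1.5e6,
                           normalize = c("grid", "set")) {
  normalize <- match.arg(normalize)
  if (is.null(spectra)) spectra <- nirsSpectra("natural")
  span <- range(cache$wavelengths)
  if (any(counts < 3))
    stop("need at least as many wavelengths as brain chromophores")
  rows <- do.call(rbind, lapply(counts, function(n) {
    w <- seq(span[1], span[2], length.out = n)
    .bandRows(cache, w, spectra, responsivity, budget,
              label = sprintf("%d wavelengths", n), normalize = normalize)
  }))
  class(rows) <- c("trnirsScan", class(rows))
  attr(rows, "best") <- .bestBand(rows)
  rows
}

#' Photon-budget sweep for one band
#'
#' Evaluates the brain cytochrome-c-oxidase uncertainty of one wavelength
#' band across a range of total photon budgets.  Because the moment
#' covariance is proportional to 1/Ntot the curve is exactly proportional
#' to 1/sqrt(budget).
#'
#' @inheritParams scanConsecutive16
#' @param bandStart first wavelength of the band, nm (on the grid).
#' @param budgets numeric vector of total photon budgets.
#' @return data.frame with columns `budget` and `sigma_uM`.
#' @export
budgetSweep <- function(cache, spectra = NULL, bandStart = 700,
                        budgets = 10^seq(5, 8, by = 0.5),
                        responsivity = NULL, nWindow = 16,
                        normalize = c("grid", "set")) {
  normalize <- match.arg(normalize)
  if (is.null(spectra)) spectra <- nirsSpectra("natural")
  if (any(budgets <= 0)) stop("budgets must be positive")
  wl <- cache$wavelengths
  i <- which(abs(wl - bandStart) < 1e-6)
  if (length(i) != 1 || i + nWindow - 1 > length(wl))
    stop("band not contained in the cached grid")
  w <- wl[i:(i + nWindow - 1)]
  sig <- vapply(budgets, function(b) {
    rows <- .bandRows(cache, w, spectra, responsivity, b, label = "",
                      normalize = normalize)
    rows$sigma_uM[rows$layer == "brain" & rows$chromophore == "oxCCO"]
  }, numeric(1))
  data.frame(budget = budgets, sigma_uM = sig)
}
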