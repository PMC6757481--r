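# DTOF statistics: clipping, central moments, the Poisson-noise covariance
# of moment changes, responsivity/budget scaling and Poisson resampling.

#' Clip a DTOF at a fraction of its maximum
#'
#' Keeps the contiguous channel range around the global maximum where
#' counts are at least `fraction` times the maximum (the conventional
#' ">= 1% of peak" region used for moment calculation) and drops the
#' channels outside it.
#'
#' @param dtof a [DTOF-class].
#' @param fraction threshold as a fraction of the peak; 0 returns the DTOF
#'   unchanged, 1 keeps only the peak channel(s).
#' @return a clipped [DTOF-class].
#' @export
clipDtof <- function(dtof, fraction = 0.01) {
  counts <- dtof@counts
  peak <- max(counts)
  if (peak <= 0) stop("all-zero DTOF: nothing to clip")
  if (fraction <= 0) return(dtof)
  thr <- fraction * peak
  ipk <- which.max(counts)
  lo <- ipk
  while (lo > 1 && counts[lo - 1] >= thr) lo <- lo - 1
  hi <- ipk
  while (hi < length(counts) && counts[hi + 1] >= thr) hi <- hi + 1
  new("DTOF", wavelength = dtof@wavelength, times = dtof@times[lo:hi],
      counts = counts[lo:hi], channelWidth = dtof@channelWidth)
}

# Clip window from a smoothed copy of the counts: with Monte Carlo
# estimated (rather than measured) DTOFs the raw channel maximum is noisy,
# so the contiguous >= fraction*peak region is located on a moving-average
# smoothed curve and then applied to the raw counts.
.smoothedClipWindow <- function(counts, fraction = 0.01, smooth = 9L) {
  if (smooth > 1L) {
    kern <- rep(1 / smooth, smooth)
    padded <- c(rep(0, smooth), counts, rep(0, smooth))
    sm <- stats::filter(padded, kern, sides = 2)
    sm <- as.numeric(sm[(smooth + 1):(smooth + length(counts))])
  } else {
    sm <- counts
  }
  peak <- max(sm)
  if (peak <= 0) stop("all-zero DTOF: nothing to clip")
  thr <- fraction * peak
  ipk <- which.max(sm)
  lo <- ipk
  while (lo > 1 && sm[lo - 1] >= thr) lo <- lo - 1
  hi <- ipk
  while (hi < length(counts) && sm[hi + 1] >= thr) hi <- hi + 1
  c(lo, hi)
}

#' Statistical moments of a DTOF
#'
#' Total counts, mean time of flight, and the second to fourth central
#' moments of the histogram: Ntot = sum N_i, <t> = sum t_i N_i / Ntot,
#' V = sum (t_i - <t>)^2 N_i / Ntot, and analogously m3c and m4c.
#'
#' @param dtof a [DTOF-class] (typically clipped first, see [clipDtof()]).
#' @return named list with elements `Ntot`, `meanT` (ps), `V` (ps^2),
#'   `m3c` (ps^3), `m4c` (ps^4) and `wavelength`.
#' @export
dtofMoments <- function(dtof) {
  N <- sum(dtof@counts)
  if (N <= 0) stop("Ntot = 0: moments undefined")
  t <- dtof@times
  p <- dtof@counts / N
  m1 <- sum(t * p)
  tc <- t - m1
  list(Ntot = N, meanT = m1, V = sum(tc^2 * p), m3c = sum(tc^3 * p),
       m4c = sum(tc^4 * p), wavelength = dtof@wavelength)
}

#' Change in DTOF moments between two states
#'
#' dA = -ln(Ntot*/Ntot), dT = <t>* - <t>, dV = V* - V, where the starred
#' state is `after`.
#'
#' @param after,before moment lists from [dtofMoments()].
#' @return named vector `c(A = , T = , V = )`.
#' @export
momentChange <- function(after, before) {
  c(A = -log(after$Ntot / before$Ntot), T = after$meanT - before$meanT,
    V = after$V - before$V)
}

#' Poisson-noise covariance of the moment changes
#'
#' Covariance matrix of (dA, dT, dV) under Poisson photon noise:
#' Z = (2/Ntot) * diag-block with Z\[A,A\] = 2/Ntot, Z\[T,T\] = 2V/Ntot,
#' Z\[T,V\] = 2 m3c/Ntot, Z\[V,V\] = 2 (m4c - V^2)/Ntot and
#' Z\[A,T\] = Z\[A,V\] = 0.  The factor 2 reflects that a change is the
#' difference of two independently noisy measurements; set
#' `pairFactor = 1` when propagating against a noiseless baseline.
#'
#' @param m moment list from [dtofMoments()].
#' @param pairFactor 2 (default, difference of two noisy measurements)
#'   or 1.
#' @return 3 x 3 symmetric matrix with dimnames A, T, V.
#' @export
covarianceZ <- function(m, pairFactor = 2) {
  if (m$Ntot <= 0) stop("Ntot must be positive")
  f <- pairFactor / m$Ntot
  Z <- matrix(0, 3, 3, dimnames = list(MOMENT_NAMES, MOMENT_NAMES))
  Z["A", "A"] <- f
  Z["T", "T"] <- f * m$V
  Z["T", "V"] <- Z["V", "T"] <- f * m$m3c
  Z["V", "V"] <- f * (m$m4c - m$V^2)
  Z
}

#' Scale DTOFs by detector responsivity and a fixed photon budget
#'
#' Multiplies each DTOF by the relative detector responsivity at its
#' wavelength (a uniform detector leaves the shapes untouched) and then
#' applies one global factor so that the summed counts across time and
#' wavelength equal `totalPhotons`.  Relative spectral shape is preserved.
#'
#' @param dtofs list of [DTOF-class] sharing the channel grid.
#' @param curve a [SpectralCurve-class] responsivity curve, or `NULL` for
#'   a spectrally uniform detector.
#' @param totalPhotons photon budget summed over the wavelength set
#'   (default 1.5e6).
#' @return list of scaled [DTOF-class] objects.
#' @export
applyResponsivityAndBudget <- function(dtofs, curve = NULL,
                                       totalPhotons = 1.5e6) {
  wl <- vapply(dtofs, function(d) d@wavelength, numeric(1))
  r <- if (is.null(curve)) rep(1, length(dtofs))
       else spectrumValues(curve, wl)
  total <- sum(mapply(function(d, ri) ri * sum(d@counts), dtofs, r))
  if (total <= 0) stop("zero total signal: cannot normalise")
  scale <- totalPhotons / total
  mapply(function(d, ri) {
    new("DTOF", wavelength = d@wavelength, times = d@times,
        counts = d@counts * ri * scale, channelWidth = d@channelWidth)
  }, dtofs, r, SIMPLIFY = FALSE)
}

#' Poisson-resample a DTOF
#'
#' Replaces each channel's expected count by an independent Poisson draw
#' with that mean; reproducible under `seed`.
#'
#' @param dtof a [DTOF-class] of expected counts.
#' @param seed RNG seed.
#' @return a [DTOF-class] with integer counts.
#' @export
poissonSample <- function(dtof, seed = NULL) {
  if (any(dtof@counts < 0)) stop("expected counts must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  new("DTOF", wavelength = dtof@wavelength, times = dtof@times,
      counts = as.numeric(rpois(length(dtof@counts), dtof@counts)),
      channelWidth = dtof@channelWidth)
}
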