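# Shared fixtures: all built in code, cached across test files so the
# expensive Monte Carlo runs happen once per test session.

.fixtures <- new.env(parent = emptyenv())

# One Monte Carlo run on the default head model, memoised.
testRun <- function(wavelength = 800, nPhotons = 2e5, seed = 314) {
  key <- sprintf("run_%g_%g_%d", wavelength, nPhotons, seed)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- mcSimulate(defaultHeadModel(), wavelength,
                                   nPhotons = nPhotons, seed = seed)
  .fixtures[[key]]
}

# Forward cache over the 25-wavelength grid, memoised.
testCache <- function(nPhotons = 5e5, seed = 42) {
  key <- sprintf("cache_%g_%d", nPhotons, seed)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- runForwardGrid(defaultHeadModel(),
                                       nPhotons = nPhotons, seed = seed)
  .fixtures[[key]]
}

# Smooth synthetic DTOF with a gamma-shaped time course (a realistic
# single-peaked reflectance curve), expected (non-integer) counts.
gammaDtof <- function(Ntot = 1e6, nChan = 128, width = 19.5, shape = 4,
                      scale = 120, wavelength = 800) {
  times <- (seq_len(nChan) - 0.5) * width
  dens <- stats::dgamma(times, shape = shape, scale = scale)
  new("DTOF", wavelength = wavelength, times = times,
      counts = Ntot * dens / sum(dens), channelWidth = width)
}

# Representative two-layer sensitivity matrix (values of the order the
# default head model produces at 800 nm; frozen so inversion tests do not
# depend on Monte Carlo noise).
refX <- function() {
  matrix(c(108, 22, -2600, -9500, -5.1e5, -4.2e6), nrow = 3, byrow = TRUE,
         dimnames = list(c("A", "T", "V"), c("scalp", "brain")))
}

# Vectorised moments of many Poisson replicates of one expected DTOF
# (columns of `draws` are replicates): Ntot, <t>, V per replicate.
replicateMoments <- function(times, draws) {
  N <- colSums(draws)
  m1 <- colSums(times * draws) / N
  V <- colSums(times^2 * draws) / N - m1^2
  list(Ntot = N, meanT = m1, V = V)
}
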