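test_that("clipping keeps the contiguous region around the peak", {
  tri <- new("DTOF", wavelength = 800, times = (1:5) * 19.5 - 9.75,
             counts = c(1, 5, 10, 5, 1), channelWidth = 19.5)
  expect_equal(clipDtof(tri, 0.3)@counts, c(5, 10, 5))
  expect_equal(clipDtof(tri, 0)@counts, tri@counts)
  expect_equal(clipDtof(tri, 1)@counts, 10)
  zero <- new("DTOF", wavelength = 800, times = tri@times,
              counts = rep(0, 5), channelWidth = 19.5)
  expect_error(clipDtof(zero), "all-zero")
})

test_that("moments match hand-computed values on degenerate histograms", {
  mk <- function(counts, width = 100) {
    new("DTOF", wavelength = 800,
        times = (seq_along(counts) - 0.5) * width, counts = counts,
        channelWidth = width)
  }
  # single populated channel at t = 450
  single <- dtofMoments(mk(c(0, 0, 0, 0, 1)))
  expect_equal(single$meanT, 450)
  expect_equal(single$V, 0)
  expect_equal(single$m3c, 0)
  # two equal channels 200 ps apart: <t> midway, V = 100^2, m3c = 0
  two <- dtofMoments(mk(c(0, 0, 0, 1, 0, 1)))
  expect_equal(two$meanT, 450)
  expect_equal(two$V, 100^2)
  expect_equal(two$m3c, 0)
  expect_equal(two$m4c, 100^4)
  # symmetric histogram has zero skew
  sym <- dtofMoments(mk(c(1, 3, 7, 3, 1)))
  expect_equal(sym$m3c, 0)
  expect_error(dtofMoments(mk(rep(0, 4))), "undefined")
})

test_that("moments of a clipped DTOF ignore sub-threshold channels", {
  d <- gammaDtof(Ntot = 1e5)
  clipped <- clipDtof(d, 0.01)
  m1 <- dtofMoments(clipped)
  # add far-out sub-threshold channels: the clip window is unchanged
  d2 <- d
  tail <- d@counts < 0.01 * max(d@counts) & d@times > 1500
  d2@counts[tail] <- d2@counts[tail] + 1e-6
  m2 <- dtofMoments(clipDtof(d2, 0.01))
  expect_equal(m2$meanT, m1$meanT)
  expect_equal(m2$V, m1$V)
})

test_that("covariance Z has the Poisson structure and scalings", {
  m <- dtofMoments(clipDtof(gammaDtof(Ntot = 2e6), 0.01))
  Z <- covarianceZ(m)
  expect_equal(Z, t(Z))
  expect_equal(Z["A", "T"], 0)
  expect_equal(Z["A", "V"], 0)
  expect_equal(Z["A", "A"], 2 / m$Ntot)
  expect_equal(Z["T", "T"], 2 * m$V / m$Ntot)
  expect_equal(Z["V", "V"], 2 * (m$m4c - m$V^2) / m$Ntot)
  # doubling Ntot at fixed shape halves every entry
  m2 <- m
  m2$Ntot <- 2 * m$Ntot
  expect_equal(covarianceZ(m2), Z / 2)
  # single-measurement variant drops the pair factor
  expect_equal(covarianceZ(m, pairFactor = 1), Z / 2)
  # symmetric DTOF: m3c = 0 so the T-V cross term vanishes
  msym <- m
  msym$m3c <- 0
  expect_equal(covarianceZ(msym)["T", "V"], 0)
})

test_that("covariance Z is symmetric positive semidefinite on random DTOFs", {
  set.seed(1203)
  for (i in 1:1000) {
    counts <- stats::rgamma(32, shape = stats::runif(1, 0.3, 4)) *
      10^stats::runif(1, 0, 4)
    d <- new("DTOF", wavelength = 800, times = (1:32 - 0.5) * 19.5,
             counts = counts, channelWidth = 19.5)
    Z <- covarianceZ(dtofMoments(d))
    expect_true(isSymmetric(Z))
    ev <- eigen(Z, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev > -1e-9 * max(ev)))
  }
})

test_that("Z matches the empirical covariance of Poisson moment changes", {
  d <- clipDtof(gammaDtof(Ntot = 1e5), 0.01)
  m <- dtofMoments(d)
  Z <- covarianceZ(m)
  nRep <- 10000
  set.seed(99)
  draws1 <- matrix(rpois(length(d@counts) * nRep, d@counts),
                   nrow = length(d@counts))
  draws2 <- matrix(rpois(length(d@counts) * nRep, d@counts),
                   nrow = length(d@counts))
  r1 <- replicateMoments(d@times, draws1)
  r2 <- replicateMoments(d@times, draws2)
  dm <- cbind(A = -log(r2$Ntot / r1$Ntot), T = r2$meanT - r1$meanT,
              V = r2$V - r1$V)
  emp <- stats::cov(dm)
  for (a in c("A", "T", "V")) for (b in c("A", "T", "V")) {
    scale <- sqrt(Z[a, a] * Z[b, b])
    expect_lt(abs(emp[a, b] - Z[a, b]) / scale, 0.05)
  }
})

test_that("responsivity and budget scaling preserve shape and total", {
  d1 <- gammaDtof(Ntot = 5e5, wavelength = 700)
  d2 <- gammaDtof(Ntot = 5e5, wavelength = 900)
  out <- applyResponsivityAndBudget(list(d1, d2), curve = NULL,
                                    totalPhotons = 1.5e6)
  expect_equal(sum(out[[1]]@counts), 7.5e5)
  expect_equal(sum(out[[2]]@counts), 7.5e5)
  expect_equal(out[[1]]@counts / sum(out[[1]]@counts),
               d1@counts / sum(d1@counts))
  # a constant curve is identical to no curve at all
  flat <- new("SpectralCurve", species = "responsivity",
              wavelengths = c(650, 950), values = c(1, 1),
              convention = "responsivity")
  outFlat <- applyResponsivityAndBudget(list(d1, d2), curve = flat)
  expect_equal(outFlat[[1]]@counts, out[[1]]@counts)
  # the declining multialkali curve starves the long wavelength
  outR <- applyResponsivityAndBudget(list(d1, d2),
                                     curve = multialkaliResponsivity())
  expect_gt(sum(outR[[1]]@counts), sum(outR[[2]]@counts))
  expect_equal(sum(outR[[1]]@counts) + sum(outR[[2]]@counts), 1.5e6)
})

test_that("Poisson resampling is reproducible and unbiased", {
  d <- gammaDtof(Ntot = 1e5)
  zero <- new("DTOF", wavelength = 800, times = d@times,
              counts = rep(0, length(d@times)), channelWidth = d@channelWidth)
  expect_equal(poissonSample(zero, seed = 5)@counts, zero@counts)
  s1 <- poissonSample(d, seed = 7)
  s2 <- poissonSample(d, seed = 7)
  expect_identical(s1@counts, s2@counts)
  # a channel with mean 1e6 lands within +-5e3 (normal approximation)
  big <- new("DTOF", wavelength = 800, times = d@times[1:2],
             counts = c(1e6, 1e6), channelWidth = d@channelWidth)
  draw <- poissonSample(big, seed = 11)@counts
  expect_true(all(abs(draw - 1e6) < 5e3))
  # law of large numbers on one channel
  mu <- d@counts[30]
  set.seed(21)
  reps <- rpois(10000, mu)
  expect_lt(abs(mean(reps) - mu), 3 * sqrt(mu / 10000))
})
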