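zFrom <- function(Ntot, dtof = gammaDtof(Ntot = 1)) {
  m <- dtofMoments(dtof)
  m$Ntot <- Ntot
  covarianceZ(m)
}

test_that("single-layer attenuation-only case has the closed form", {
  X <- refX()[, "brain", drop = FALSE]
  Z <- zFrom(2.4e5)
  out <- sigmaDmua(X, Z, moments = "A")
  expect_equal(unname(out$sigma),
               sqrt(2 / 2.4e5) / X["A", 1], tolerance = 1e-12)
})

test_that("uncertainty scales inversely with the sensitivity matrix", {
  Z <- zFrom(1e6)
  s1 <- sigmaDmua(refX(), Z)$sigma
  s3 <- sigmaDmua(3 * refX(), Z)$sigma
  expect_equal(s3, s1 / 3, tolerance = 1e-12)
})

test_that("rank-deficient sensitivities raise identifiability errors", {
  X <- refX()
  X[, "brain"] <- 2 * X[, "scalp"]
  expect_error(suppressWarnings(sigmaDmua(X, zFrom(1e6))), "singular")
})

test_that("moment subsets are nested in information content", {
  Z <- zFrom(1.5e6 / 16)
  X <- refX()
  # one recoverable layer: attenuation alone, then adding T, then adding V
  Xb <- X[, "brain", drop = FALSE]
  sigA <- sigmaDmua(Xb, Z, moments = "A")$sigma
  sigAT <- sigmaDmua(Xb, Z, moments = c("A", "T"))$sigma
  sigATV <- sigmaDmua(Xb, Z)$sigma
  expect_lte(sigAT, sigA + 1e-15)
  expect_lte(sigATV, sigAT + 1e-15)
  # two layers need at least two moments; A alone is under-determined
  expect_error(sigmaDmua(X, Z, moments = "A"), "under-determined")
  sig2AT <- sigmaDmua(X, Z, moments = c("A", "T"))$sigma
  sig2ATV <- sigmaDmua(X, Z)$sigma
  expect_true(all(sig2ATV <= sig2AT + 1e-15))
})

test_that("noise-free synthetic moment changes invert exactly", {
  X <- refX()
  Z <- zFrom(1e6)
  truth <- c(scalp = 3e-4, brain = -2e-4)
  dm <- as.vector(X %*% truth)
  names(dm) <- c("A", "T", "V")
  out <- recoverDmua(dm, X, Z)
  expect_equal(out$dmua, truth, tolerance = 1e-10)
  zero <- recoverDmua(c(A = 0, T = 0, V = 0), X, Z)
  expect_equal(unname(zero$dmua), c(0, 0))
})

test_that("small perturbations recovered end-to-end from the MC chain", {
  r <- testRun(800, 1e6, seed = 881)
  X <- twoLayerX(sensitivityFactors(r))
  base <- simDtof(r)
  win <- clipDtof(base, 0.01)
  lo <- which(base@times == win@times[1])
  hi <- which(base@times == win@times[length(win@times)])
  windowed <- function(d)
    new("DTOF", wavelength = d@wavelength, times = d@times[lo:hi],
        counts = d@counts[lo:hi], channelWidth = d@channelWidth)
  m0 <- dtofMoments(windowed(base))
  delta <- c(0, 0, 1e-4)
  m1 <- dtofMoments(windowed(absorptionReweight(r, delta)))
  dm <- momentChange(m1, m0)
  out <- recoverDmua(dm, X, covarianceZ(m0))
  expect_equal(unname(out$dmua["brain"]), 1e-4, tolerance = 0.1)
  expect_lt(abs(out$dmua["scalp"]), 5e-5)
})

test_that("GLS dispersion matches the error-propagation prediction", {
  d <- clipDtof(gammaDtof(Ntot = 2e5), 0.01)
  m <- dtofMoments(d)
  Z <- covarianceZ(m)
  X <- refX()
  pred <- sigmaDmua(X, Z)$sigma
  nRep <- 10000
  set.seed(4242)
  draws1 <- matrix(rpois(length(d@counts) * nRep, d@counts),
                   nrow = length(d@counts))
  draws2 <- matrix(rpois(length(d@counts) * nRep, d@counts),
                   nrow = length(d@counts))
  r1 <- replicateMoments(d@times, draws1)
  r2 <- replicateMoments(d@times, draws2)
  dm <- rbind(A = -log(r2$Ntot / r1$Ntot), T = r2$meanT - r1$meanT,
              V = r2$V - r1$V)
  # vectorised GLS solve: dmua = (X' Z^-1 X)^-1 X' Z^-1 dm
  s <- sqrt(diag(Z))
  Xn <- X / s
  Zn <- Z / tcrossprod(s)
  G <- solve(crossprod(Xn, solve(Zn, Xn)), crossprod(Xn, solve(Zn)))
  est <- G %*% (dm / s)
  sdEmp <- apply(est, 1, stats::sd)
  expect_lt(abs(sdEmp["scalp"] - pred["scalp"]) / pred["scalp"], 0.05)
  expect_lt(abs(sdEmp["brain"] - pred["brain"]) / pred["brain"], 0.05)
})

test_that("Beer-Lambert propagation has its closed forms and scalings", {
  sp <- nirsSpectra("natural")
  wl <- c(760, 800, 850, 900)
  sigma <- matrix(c(2e-4, 3e-4, 2.5e-4, 4e-4,
                    4e-4, 6e-4, 5e-4, 8e-4), ncol = 2,
                  dimnames = list(NULL, c("scalp", "brain")))
  out <- sigmaDC(sigma, wl, sp)
  expect_identical(out$layer, c("scalp", "scalp", rep("brain", 3)))
  expect_true(all(out$sigma_uM > 0))
  # homogeneity: scaling every sigma_dmua scales every sigma_dC
  out2 <- sigmaDC(3 * sigma, wl, sp)
  expect_equal(out2$sigma_uM, 3 * out$sigma_uM, tolerance = 1e-12)
  # square case equals the direct inverse-matrix propagation
  wl2 <- c(760, 850)
  E <- extinctionMatrix(sp, wl2, c("HbO2", "Hb"))
  s2 <- sigma[1:2, , drop = FALSE]
  sq <- sigmaDC(s2, wl2, sp,
                layerChromophores = list(scalp = c("HbO2", "Hb")))
  Einv <- solve(E)
  covDirect <- Einv %*% diag(s2[, "scalp"]^2) %*% t(Einv)
  expect_equal(sq$sigma_uM, unname(sqrt(diag(covDirect))),
               tolerance = 1e-10)
  # weighted and unweighted coincide for square systems
  squw <- sigmaDC(s2, wl2, sp, weighted = FALSE,
                  layerChromophores = list(scalp = c("HbO2", "Hb")))
  expect_equal(squw$sigma_uM, sq$sigma_uM, tolerance = 1e-10)
})

test_that("orthonormal synthetic spectra decouple the chromophores", {
  wl <- c(700, 800, 900)
  mkCurve <- function(name, values)
    new("SpectralCurve", species = name, wavelengths = wl, values = values,
        convention = "natural")
  sp <- list(a = mkCurve("a", c(1, 0, 0)), b = mkCurve("b", c(0, 1, 0)),
             c = mkCurve("c", c(0, 0, 1)))
  sigma <- matrix(c(1e-4, 2e-4, 3e-4), ncol = 1,
                  dimnames = list(NULL, "brain"))
  out <- sigmaDC(sigma, wl, sp, weighted = TRUE,
                 layerChromophores = list(brain = c("a", "b", "c")))
  expect_equal(out$sigma_uM, c(1e-4, 2e-4, 3e-4), tolerance = 1e-10)
})

test_that("adding a wavelength never increases concentration uncertainty", {
  sp <- nirsSpectra("natural")
  wl <- defaultWavelengthGrid()
  set.seed(8)
  sigAll <- matrix(stats::runif(50, 1e-4, 6e-4), ncol = 2,
                   dimnames = list(NULL, c("scalp", "brain")))
  prev <- NULL
  for (k in c(4, 8, 12, 16, 20, 25)) {
    idx <- round(seq(1, 25, length.out = k))
    out <- sigmaDC(sigAll[idx, , drop = FALSE], wl[idx], sp)
    if (!is.null(prev)) {
      nested <- all(round(seq(1, 25, length.out = kPrev)) %in% idx)
      if (nested) expect_true(all(out$sigma_uM <= prev$sigma_uM + 1e-12))
    }
    prev <- out
    kPrev <- k
  }
  # explicit nested pair
  o16 <- sigmaDC(sigAll[1:16, ], wl[1:16], sp)
  o17 <- sigmaDC(sigAll[1:17, ], wl[1:17], sp)
  expect_true(all(o17$sigma_uM <= o16$sigma_uM + 1e-12))
})

test_that("under-determined or degenerate wavelength sets are refused", {
  sp <- nirsSpectra("natural")
  sigma <- matrix(c(1e-4, 1e-4), ncol = 2,
                  dimnames = list(NULL, c("scalp", "brain")))
  expect_error(sigmaDC(sigma[1, , drop = FALSE], 800, sp), "fewer wavelengths")
  sig2 <- matrix(rep(1e-4, 4), ncol = 2,
                 dimnames = list(NULL, c("scalp", "brain")))
  expect_error(sigmaDC(sig2, c(800, 800), sp, layerChromophores =
                         list(scalp = c("HbO2", "Hb"))),
               "rank|increasing")
})
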