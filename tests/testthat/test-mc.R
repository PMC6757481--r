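# Monte Carlo kernel physics: bookkeeping, determinism, pathlength
# identities, reweighting exactness and the diffusion-theory oracle.

test_that("identical seeds give bit-identical results and tallies balance", {
  r1 <- mcSimulate(defaultHeadModel(), 800, nPhotons = 3e4, seed = 5)
  r2 <- mcSimulate(defaultHeadModel(), 800, nPhotons = 3e4, seed = 5)
  expect_identical(r1@photons, r2@photons)
  expect_identical(r1@tallies, r2@tallies)
  r3 <- mcSimulate(defaultHeadModel(), 800, nPhotons = 3e4, seed = 6)
  expect_false(identical(r1@tallies, r3@tallies))
  # every launched packet is accounted for exactly
  expect_equal(sum(r1@tallies), r1@nLaunched, tolerance = 1e-12)
  # absorption bookkeeping: surviving + absorbed weight equals the
  # detected unit-weight count
  w <- exp(-as.vector(r1@photons[, -1] %*% r1@mua))
  survived <- sum(w)
  absorbed <- nrow(r1@photons) - survived
  expect_equal(survived + absorbed + unname(r1@tallies["topOutside"]) +
                 unname(r1@tallies["side"]) + unname(r1@tallies["bottom"]) +
                 unname(r1@tallies["expired"]),
               r1@nLaunched, tolerance = 1e-9)
})

test_that("total pathlength equals in-medium speed times time of flight", {
  r <- testRun(800, 2e5)
  v <- lightSpeed(r@refractiveIndex)
  expect_equal(r@photons[, "t"] * v,
               rowSums(r@photons[, -1, drop = FALSE]),
               tolerance = 1e-9)
  # hence the weighted identity sum_j MPP_j = v <t>
  s <- sensitivityFactors(r)
  w <- exp(-as.vector(r@photons[, -1] %*% r@mua))
  tbar <- sum(w * r@photons[, "t"]) / sum(w)
  expect_equal(sum(s@factors["MPP", ]), v * tbar, tolerance = 1e-9)
})

test_that("partial pathlengths are largest in skull, then scalp, then brain", {
  s <- sensitivityFactors(testRun(800, 2e5))@factors
  expect_gt(s["MPP", "skull"], s["MPP", "scalp"])
  expect_gt(s["MPP", "scalp"], s["MPP", "brain"])
  # deeper layers dominate the higher-moment sensitivities
  expect_gt(abs(s["MTSF", "brain"]), abs(s["MTSF", "scalp"]))
  expect_gt(abs(s["VSF", "brain"]), abs(s["VSF", "scalp"]))
})

test_that("sensitivity factors equal reweighting finite differences", {
  r <- testRun(800, 2e5)
  s <- sensitivityFactors(r)@factors
  L <- r@photons[, -1, drop = FALSE]
  t <- r@photons[, "t"]
  momAt <- function(mua) {
    w <- exp(-as.vector(L %*% mua))
    W <- sum(w)
    tbar <- sum(w * t) / W
    c(A = -log(W), meanT = tbar, V = sum(w * (t - tbar)^2) / W)
  }
  h <- 1e-6
  for (j in 1:3) {
    dm <- (momAt(r@mua + h * (1:3 == j)) - momAt(r@mua - h * (1:3 == j))) /
      (2 * h)
    expect_equal(unname(dm["A"]), unname(s["MPP", j]), tolerance = 1e-6)
    expect_equal(unname(dm["meanT"]), unname(s["MTSF", j]), tolerance = 1e-5)
    expect_equal(unname(dm["V"]), unname(s["VSF", j]), tolerance = 1e-5)
  }
})

test_that("absorption reweighting is exact", {
  r <- testRun(800, 2e5)
  base <- simDtof(r)
  # identity at zero perturbation
  expect_equal(absorptionReweight(r, c(0, 0, 0))@counts, base@counts)
  # any positive perturbation reduces counts and advances the mean time
  up <- absorptionReweight(r, c(0, 0, 5e-3))
  expect_lt(sum(up@counts), sum(base@counts))
  expect_lt(dtofMoments(up)$meanT, dtofMoments(base)$meanT)
  # a global perturbation acts channel-wise as exp(-v dmua t) with the
  # exact times; with 19.5 ps bins the channel-centre approximation holds
  # to first order in the channel width
  d <- 1e-3
  glob <- absorptionReweight(r, rep(d, 3))
  v <- lightSpeed(r@refractiveIndex)
  keep <- base@counts > 0
  ratio <- glob@counts[keep] / base@counts[keep]
  expect_equal(ratio, exp(-v * d * base@times[keep]), tolerance = 1e-3)
  # over-large negative perturbations are refused
  expect_error(absorptionReweight(r, -r@mua), "non-positive")
})

test_that("reweighted and re-simulated perturbed runs agree within noise", {
  m0 <- defaultHeadModel()
  delta <- c(0, 0, 2e-3)
  r0 <- mcSimulate(m0, 800, nPhotons = 4e5, seed = 77)
  r1 <- mcSimulate(m0, 800, nPhotons = 4e5, seed = 1234)
  mRw <- dtofMoments(absorptionReweight(r0, delta))
  mRe <- dtofMoments(simDtof(r1, mua = r1@mua + delta))
  se0 <- momentStandardErrors(r0, r0@mua + delta)
  se1 <- momentStandardErrors(r1, r1@mua + delta)
  se <- sqrt(se0^2 + se1^2)
  expect_lt(abs(mRw$Ntot - mRe$Ntot), 3 * se["Ntot"])
  expect_lt(abs(mRw$meanT - mRe$meanT), 3 * se["meanT"])
  expect_lt(abs(mRw$V - mRe$V), 3 * se["V"])
})

test_that("homogeneous-medium kernel matches diffusion theory", {
  # one thick layer: effectively a semi-infinite homogeneous medium
  layer <- layerSpec("scalp", thickness = 80, cHbO2 = 50, cHb = 20,
                     backgroundMua = 0.005, scatterA = 2 * 800^1.4,
                     scatterB = 1.4)
  m <- tissueModel(layers = list(layer), wavelengths = c(800))
  r <- mcSimulate(m, 800, nPhotons = 2e6, seed = 31)
  d <- simDtof(r)
  v <- lightSpeed(1.4)
  times <- d@times
  th <- diffusionReflectance(r@mua, r@musp, 1.4, 30, times)
  # the mean times of flight of the two solutions agree closely
  expect_equal(sum(times * d@counts) / sum(d@counts),
               sum(times * th) / sum(th), tolerance = 0.05)
  # shape agreement after the peak, on 4-channel blocks to tame the
  # sparse-count noise of the reduced-statistics run
  ipk <- which.max(d@counts)
  sel <- seq(ipk + 4, ipk + 43)
  block <- function(x) tapply(x, rep(seq_len(10), each = 4), sum)
  mc <- block(d@counts[sel]); mc <- mc / sum(mc)
  dt <- block(th[sel]); dt <- dt / sum(dt)
  expect_lt(max(abs(log(mc / dt))), 0.35)
  # the asymptotic late-time log-slope of the diffusion curve is -v mua
  tt <- seq(5e4, 1e5, by = 1e3)
  thl <- diffusionReflectance(r@mua, r@musp, 1.4, 30, tt)
  slope <- stats::coef(stats::lm(log(thl) ~ tt))[2]
  expect_equal(unname(slope), unname(-v * r@mua), tolerance = 0.02)
  # doubling mua scales the diffusion curve by exp(-v dmua t) exactly
  th2 <- diffusionReflectance(2 * r@mua, r@musp, 1.4, 30, times)
  expect_equal(th2 / th, exp(-v * r@mua * times), tolerance = 1e-9)
})

test_that("degenerate inputs are refused", {
  m <- defaultHeadModel()
  expect_error(mcSimulate(m, 800, nPhotons = 0), "at least 1")
  expect_error(mcSimulate(m, 801), "not on the model grid")
})
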