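# Monte Carlo forward model: simulation driver, DTOF construction,
# absorption reweighting, sensitivity factors and the diffusion-theory
# cross-check oracle.

C_MM_PER_PS <- 0.299792458

#' Speed of light in the medium
#'
#' @param refractiveIndex dimensionless.
#' @return mm per ps.
#' @export
lightSpeed <- function(refractiveIndex) C_MM_PER_PS / refractiveIndex

#' Default simulation geometry
#'
#' 120 x 120 x 80 mm slab, source at the centre of the top face, annular
#' detector of radii 28.5-31.5 mm (nominal source-detector separation
#' 30 mm), 128 time channels of 19.5 ps, air above the slab.
#'
#' @param slabXY,slabZ slab side and depth, mm.
#' @param ringInner,ringOuter annulus radii, mm.
#' @param nChannels,channelWidth timing grid.
#' @param ambientIndex index above the surface.
#' @return a [Geometry-class].
#' @export
defaultGeometry <- function(slabXY = 120, slabZ = 80, ringInner = 28.5,
                            ringOuter = 31.5, nChannels = 128L,
                            channelWidth = 19.5, ambientIndex = 1.0) {
  new("Geometry", slabXY = slabXY, slabZ = slabZ, ringInner = ringInner,
      ringOuter = ringOuter, nChannels = as.integer(nChannels),
      channelWidth = channelWidth, ambientIndex = ambientIndex)
}

#' Timing grid preset matching the laboratory instrument
#'
#' 1024 channels of 13.68 ps instead of the simulation default
#' (128 x 19.5 ps).
#'
#' @param ... further arguments passed to [defaultGeometry()].
#' @return a [Geometry-class].
#' @export
instrumentGeometry <- function(...) {
  defaultGeometry(nChannels = 1024L, channelWidth = 13.68, ...)
}

.modelColumn <- function(model, wavelength) {
  i <- which(abs(model@wavelengths - wavelength) < 1e-6)
  if (length(i) != 1)
    stop("wavelength ", wavelength, " nm is not on the model grid")
  i
}

#' Run the Monte Carlo forward simulation at one wavelength
#'
#' Launches photon packets at the centre of the top face and follows them
#' through the layered slab.  Scattering is handled in the similarity
#' regime by default (isotropic scattering with mu_s = mu_s'); layers with
#' a nonzero anisotropy g use Henyey-Greenstein phase sampling with
#' mu_s = mu_s'/(1 - g).  Fresnel/total-internal reflection is applied at
#' the top surface; packets crossing the top within the detector annulus
#' before the last time channel are recorded with their exact time of
#' flight and per-layer partial pathlengths.  Transport is absorption-free;
#' absorption enters as a deterministic per-photon weight when DTOFs or
#' sensitivity factors are computed (see [simDtof()]).
#'
#' @param model a [TissueModel-class].
#' @param wavelength nm, must be on the model grid.
#' @param geometry a [Geometry-class].
#' @param nPhotons photon packets to launch.
#' @param seed master RNG seed (integer).
#' @return a [SimResult-class].
#' @export
mcSimulate <- function(model, wavelength, geometry = defaultGeometry(),
                       nPhotons = 1e6, seed = 1) {
  if (nPhotons < 1) stop("nPhotons must be at least 1")
  i <- .modelColumn(model, wavelength)
  mua <- model@mua[, i]
  musp <- model@musp[, i]
  if (any(!is.finite(mua)) || any(mua < 0) || any(musp <= 0))
    stop("non-physical optical properties")
  g <- vapply(model@layers, function(l) l@anisotropy, numeric(1))
  n <- vapply(model@layers, function(l) l@refractiveIndex, numeric(1))
  if (length(unique(n)) > 1)
    warning("layer refractive indices differ; using the first layer's value")
  nMedium <- n[1]
  thick <- layerThicknesses(model)
  zb <- c(0, cumsum(thick))
  zb[length(zb)] <- max(zb[length(zb) - 1] + 1e-6, geometry@slabZ)
  mus <- ifelse(g > 0, musp / (1 - g), musp)
  tMax <- geometry@nChannels * geometry@channelWidth
  out <- .mc_kernel(nPhotons, seed, zb, mus, g, nMedium,
                    geometry@ambientIndex, geometry@slabXY / 2,
                    geometry@ringInner, geometry@ringOuter, tMax,
                    lightSpeed(nMedium))
  photons <- out$photons
  colnames(photons) <- c("t", paste0("l_", vapply(model@layers,
                                                  function(l) l@name,
                                                  character(1))))
  new("SimResult", photons = photons, tallies = out$tallies,
      nLaunched = nPhotons, seed = seed, wavelength = wavelength,
      mua = mua, musp = musp, refractiveIndex = nMedium,
      geometry = geometry)
}

.photonWeights <- function(result, mua) {
  L <- result@photons[, -1, drop = FALSE]
  if (length(mua) != ncol(L)) stop("need one mua per layer")
  if (any(mua < 0)) stop("absorption must be non-negative")
  exp(-as.vector(L %*% mua))
}

#' Build the DTOF of a finished run
#'
#' Bins the detected photons by time of flight and applies the microscopic
#' Beer-Lambert absorption weight exp(-sum_j mua_j l_j), yielding the
#' expected DTOF for the given per-layer absorption (by default the one
#' the run was configured with).
#'
#' @param result a [SimResult-class].
#' @param mua per-layer absorption, mm^-1.
#' @return a [DTOF-class] (expected, non-integer counts).
#' @export
simDtof <- function(result, mua = result@mua) {
  geo <- result@geometry
  w <- .photonWeights(result, mua)
  chan <- pmin(floor(result@photons[, "t"] / geo@channelWidth),
               geo@nChannels - 1L)
  counts <- as.vector(tapply(w, factor(chan, levels = 0:(geo@nChannels - 1L)),
                             sum, default = 0))
  new("DTOF", wavelength = result@wavelength,
      times = (seq_len(geo@nChannels) - 0.5) * geo@channelWidth,
      counts = counts, channelWidth = geo@channelWidth)
}

#' Reweight a finished run to a perturbed absorption
#'
#' Returns the DTOF the same photon ensemble would produce under
#' mua + delta, exactly (not linearised): each photon's weight is
#' multiplied by exp(-sum_j delta_j l_j).
#'
#' @param result a [SimResult-class].
#' @param deltaMua per-layer absorption change, mm^-1.
#' @return a [DTOF-class].
#' @export
absorptionReweight <- function(result, deltaMua) {
  if (length(deltaMua) == 1) deltaMua <- rep(deltaMua, length(result@mua))
  newMua <- result@mua + deltaMua
  if (any(newMua <= 0))
    stop("perturbation drives absorption non-positive")
  simDtof(result, mua = newMua)
}

#' Sensitivity factors of the DTOF moments
#'
#' Computes, for every layer j, the mean partial pathlength
#' MPP_j = <l_j> (the weighted average over detected photons) and the
#' first-order derivatives of the mean time of flight and variance with
#' respect to the layer absorption:
#' MTSF_j = d<t>/dmua_j = -cov(t, l_j) and
#' VSF_j = dV/dmua_j = -cov((t - <t>)^2, l_j),
#' all weighted by the Beer-Lambert absorption weights.  With these signs
#' dA = sum_j MPP_j dmua_j, dT = sum_j MTSF_j dmua_j,
#' dV = sum_j VSF_j dmua_j, where dA = -ln(Ntot*/Ntot).
#'
#' @param result a [SimResult-class].
#' @param mua per-layer absorption, mm^-1 (defaults to the run's own).
#' @return a [SensitivityMatrix-class] covering all layers.
#' @export
sensitivityFactors <- function(result, mua = result@mua) {
  if (nrow(result@photons) == 0)
    stop("no detected photons: moments undefined")
  w <- .photonWeights(result, mua)
  W <- sum(w)
  t <- result@photons[, "t"]
  L <- result@photons[, -1, drop = FALSE]
  mpp <- colSums(w * L) / W
  tbar <- sum(w * t) / W
  mtsf <- -(colSums(w * t * L) / W - tbar * mpp)
  tc2 <- (t - tbar)^2
  v <- sum(w * tc2) / W
  vsf <- -(colSums(w * tc2 * L) / W - v * mpp)
  factors <- rbind(MPP = mpp, MTSF = mtsf, VSF = vsf)
  colnames(factors) <- sub("^l_", "", colnames(L))
  new("SensitivityMatrix", factors = factors,
      wavelength = result@wavelength)
}

#' Extract the two-layer sensitivity matrix X
#'
#' The moments-method inversion treats the skull as optically constant;
#' X keeps the scalp and brain columns of the full sensitivity matrix
#' (rows A, T, V).
#'
#' @param sens a [SensitivityMatrix-class].
#' @param layers columns to keep.
#' @return 3 x 2 numeric matrix with rows `A`, `T`, `V`.
#' @export
twoLayerX <- function(sens, layers = c("scalp", "brain")) {
  X <- sens@factors[, layers, drop = FALSE]
  rownames(X) <- MOMENT_NAMES
  X
}

#' Monte Carlo standard errors of the DTOF moments
#'
#' Ensemble standard errors of Ntot, <t> and V of a finished run under the
#' given absorption, from the weighted per-photon statistics (delta-method
#' for the variance).  Used to set tolerances when comparing reweighted
#' and re-simulated runs.
#'
#' @param result a [SimResult-class].
#' @param mua per-layer absorption, mm^-1.
#' @return named vector with elements `Ntot`, `meanT`, `V` (Ntot on the
#'   detected-weight scale of the run).
#' @export
momentStandardErrors <- function(result, mua = result@mua) {
  w <- .photonWeights(result, mua)
  W <- sum(w)
  n <- result@nLaunched
  t <- result@photons[, "t"]
  tbar <- sum(w * t) / W
  v <- sum(w * (t - tbar)^2) / W
  seN <- sqrt(max(sum(w^2) - W^2 / n, 0))
  seT <- sqrt(sum(w^2 * (t - tbar)^2)) / W
  seV <- sqrt(sum(w^2 * ((t - tbar)^2 - v)^2)) / W
  c(Ntot = seN, meanT = seT, V = seV)
}

#' Time-domain diffusion reflectance of a semi-infinite medium
#'
#' Analytical diffusion-approximation reflectance at distance `rho` from
#' the source for a homogeneous semi-infinite medium: isotropic point
#' source at depth z0 = 1/mu_s' with the extrapolated-boundary (dipole
#' image) condition, using the standard internal-reflection parameter for
#' the refractive-index mismatch.  Serves as an independent cross-check
#' oracle for the Monte Carlo kernel on homogeneous models; its late-time
#' logarithmic slope is -v mu_a.
#'
#' @param mua,musp optical properties, mm^-1 (diffusion regime requires
#'   musp >> mua).
#' @param refractiveIndex medium index.
#' @param rho source-detector distance, mm.
#' @param times ps grid.
#' @return reflectance per unit time and area (arbitrary overall scale for
#'   shape comparisons), same length as `times`.
#' @export
diffusionReflectance <- function(mua, musp, refractiveIndex, rho, times) {
  stopifnot(rho > 0, mua >= 0, musp > 0)
  v <- lightSpeed(refractiveIndex)
  D <- 1 / (3 * musp)
  z0 <- 1 / musp
  # internal-reflection parameter for the index mismatch (empirical
  # polynomial in the relative index), extrapolated boundary at 2AD
  n <- refractiveIndex
  rd <- -1.440 / n^2 + 0.710 / n + 0.668 + 0.0636 * n
  A <- (1 + rd) / (1 - rd)
  zb <- 2 * A * D
  zp <- z0 + 2 * zb
  t <- pmax(times, 1e-12)
  dvt4 <- 4 * D * v * t
  (4 * pi * D * v)^(-3 / 2) * t^(-5 / 2) * exp(-rho^2 / dvt4) *
    exp(-mua * v * t) *
    (z0 * exp(-z0^2 / dvt4) + zp * exp(-zp^2 / dvt4))
}
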