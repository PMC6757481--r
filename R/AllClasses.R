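#' @import methods
#' @importFrom stats spline approx rpois setNames filter rcond
#' @importFrom utils read.table write.csv head tail
#' @useDynLib trnirs, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

LAYER_NAMES <- c("scalp", "skull", "brain")
MOMENT_NAMES <- c("A", "T", "V")

#' SpectralCurve: a tabulated wavelength-resolved quantity
#'
#' Holds one tabulated curve over wavelength: a chromophore specific
#' extinction spectrum, a water/lipid absorption spectrum, or a detector
#' responsivity characteristic.  The `convention` slot records how the
#' values are to be interpreted: `"decadic"` (base-10 extinction, as
#' compilations print them), `"natural"` (ln-based extinction), `"mua"`
#' (an absolute absorption coefficient per unit volume fraction) or
#' `"responsivity"` (dimensionless relative efficiency).
#'
#' @slot species character label (e.g. `"HbO2"`).
#' @slot wavelengths numeric, nm, strictly increasing.
#' @slot values numeric, same length; for extinction spectra the units are
#'   mm^-1 per micromolar (after unit normalisation at load).
#' @slot convention one of `"decadic"`, `"natural"`, `"mua"`,
#'   `"responsivity"`.
#' @exportClass SpectralCurve
setClass("SpectralCurve",
  representation(species = "character", wavelengths = "numeric",
                 values = "numeric", convention = "character"))

setValidity("SpectralCurve", function(object) {
  msg <- NULL
  if (length(object@wavelengths) != length(object@values))
    msg <- c(msg, "wavelengths and values must have equal length")
  if (length(object@wavelengths) > 1 && any(diff(object@wavelengths) <= 0))
    msg <- c(msg, "wavelengths must be strictly increasing")
  if (any(!is.finite(object@values)) || any(object@values < 0))
    msg <- c(msg, "values must be finite and non-negative")
  if (!object@convention %in% c("decadic", "natural", "mua", "responsivity"))
    msg <- c(msg, "unknown convention")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "SpectralCurve", function(object) {
  cat(sprintf("SpectralCurve '%s' (%s), %d nodes over %.1f-%.1f nm\n",
              object@species, object@convention,
              length(object@wavelengths),
              min(object@wavelengths), max(object@wavelengths)))
})

#' LayerSpec: composition and optical parameters of one tissue layer
#'
#' @slot name layer label, one of `"scalp"`, `"skull"`, `"brain"`.
#' @slot thickness mm; ignored when `semiInfinite` (the layer extends to
#'   the bottom of the simulation slab).
#' @slot semiInfinite logical.
#' @slot cHbO2,cHb micromolar hemoglobin concentrations.
#' @slot waterFraction,lipidFraction volume fractions in percent.
#' @slot cCCO,cCytB,cCytC micromolar cytochrome concentrations; cytochrome
#'   b and c contribute static absorption only.
#' @slot backgroundMua constant wavelength-independent absorption, mm^-1.
#' @slot muaConstant logical; when TRUE the layer absorption equals
#'   `backgroundMua` at every wavelength (used for the skull).
#' @slot scatterA scattering amplitude a in mu_s' = a * lambda^-b
#'   (mm^-1 when lambda is expressed in nm).
#' @slot scatterB scattering power b (dimensionless).
#' @slot refractiveIndex dimensionless, >= 1.
#' @slot anisotropy scattering anisotropy g used when the kernel is run
#'   outside the similarity (isotropic) regime.
#' @exportClass LayerSpec
setClass("LayerSpec",
  representation(name = "character", thickness = "numeric",
                 semiInfinite = "logical",
                 cHbO2 = "numeric", cHb = "numeric",
                 waterFraction = "numeric", lipidFraction = "numeric",
                 cCCO = "numeric", cCytB = "numeric", cCytC = "numeric",
                 backgroundMua = "numeric", muaConstant = "logical",
                 scatterA = "numeric", scatterB = "numeric",
                 refractiveIndex = "numeric", anisotropy = "numeric"))

setValidity("LayerSpec", function(object) {
  msg <- NULL
  if (!object@semiInfinite && object@thickness <= 0)
    msg <- c(msg, "thickness must be positive")
  conc <- c(object@cHbO2, object@cHb, object@cCCO, object@cCytB,
            object@cCytC, object@waterFraction, object@lipidFraction)
  if (any(conc < 0)) msg <- c(msg, "concentrations must be non-negative")
  if (object@refractiveIndex < 1) msg <- c(msg, "refractive index must be >= 1")
  if (object@anisotropy < 0 || object@anisotropy >= 1)
    msg <- c(msg, "anisotropy must lie in [0, 1)")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "LayerSpec", function(object) {
  cat(sprintf("LayerSpec '%s': %s, HbO2 %.1f uM, Hb %.1f uM, water %.1f%%\n",
              object@name,
              if (object@semiInfinite) "semi-infinite"
              else sprintf("%.1f mm", object@thickness),
              object@cHbO2, object@cHb, object@waterFraction))
})

#' TissueModel: layered head model with wavelength-resolved optics
#'
#' @slot layers list of [LayerSpec-class] ordered from the surface down.
#' @slot wavelengths nm grid.
#' @slot mua matrix (layer x wavelength), mm^-1.
#' @slot musp matrix (layer x wavelength), mm^-1.
#' @slot convention extinction convention used to build `mua`
#'   (`"decadic"` or `"natural"`).
#' @exportClass TissueModel
setClass("TissueModel",
  representation(layers = "list", wavelengths = "numeric",
                 mua = "matrix", musp = "matrix", convention = "character"))

setValidity("TissueModel", function(object) {
  msg <- NULL
  nl <- length(object@layers)
  if (!all(vapply(object@layers, is, logical(1), "LayerSpec")))
    msg <- c(msg, "layers must be LayerSpec objects")
  if (nrow(object@mua) != nl || nrow(object@musp) != nl)
    msg <- c(msg, "mua/musp must have one row per layer")
  if (ncol(object@mua) != length(object@wavelengths) ||
      ncol(object@musp) != length(object@wavelengths))
    msg <- c(msg, "mua/musp must have one column per wavelength")
  if (any(object@mua <= 0)) msg <- c(msg, "mua must be positive everywhere")
  if (any(object@musp <= 0)) msg <- c(msg, "musp must be positive everywhere")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "TissueModel", function(object) {
  cat(sprintf("TissueModel: %d layers (%s), %d wavelengths %.1f-%.1f nm, %s extinction\n",
              length(object@layers),
              paste(vapply(object@layers, function(l) l@name, character(1)),
                    collapse = ", "),
              length(object@wavelengths), min(object@wavelengths),
              max(object@wavelengths), object@convention))
})

#' Geometry: source-detector and timing geometry of the simulation
#'
#' Defaults follow the reflectance ring-detector construction: a
#' 120 x 120 x 80 mm slab, source at the centre of the top face, an annular
#' detector of radii 28.5-31.5 mm around the source, and 128 time channels
#' of 19.5 ps.
#'
#' @slot slabXY,slabZ slab side length and depth, mm.
#' @slot ringInner,ringOuter annulus radii, mm.
#' @slot nChannels number of time channels.
#' @slot channelWidth ps.
#' @slot ambientIndex refractive index of the medium above the slab.
#' @exportClass Geometry
setClass("Geometry",
  representation(slabXY = "numeric", slabZ = "numeric",
                 ringInner = "numeric", ringOuter = "numeric",
                 nChannels = "integer", channelWidth = "numeric",
                 ambientIndex = "numeric"))

setValidity("Geometry", function(object) {
  msg <- NULL
  if (object@ringInner <= 0 || object@ringOuter <= object@ringInner)
    msg <- c(msg, "need 0 < ringInner < ringOuter")
  if (object@nChannels < 1L) msg <- c(msg, "need at least one time channel")
  if (object@channelWidth <= 0) msg <- c(msg, "channelWidth must be positive")
  if (object@slabXY <= 0 || object@slabZ <= 0)
    msg <- c(msg, "slab dimensions must be positive")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "Geometry", function(object) {
  cat(sprintf("Geometry: slab %.0fx%.0fx%.0f mm, ring %.1f-%.1f mm, %d x %.2f ps channels\n",
              object@slabXY, object@slabXY, object@slabZ, object@ringInner,
              object@ringOuter, object@nChannels, object@channelWidth))
})

#' DTOF: distribution of time of flight of photons
#'
#' A histogram of (possibly expected, i.e. non-integer) photon counts over
#' uniformly spaced time channels at one wavelength.
#'
#' @slot wavelength nm.
#' @slot times channel centres, ps, uniformly spaced.
#' @slot counts photon counts (or expected counts) per channel.
#' @slot channelWidth ps.
#' @exportClass DTOF
setClass("DTOF",
  representation(wavelength = "numeric", times = "numeric",
                 counts = "numeric", channelWidth = "numeric"))

setValidity("DTOF", function(object) {
  msg <- NULL
  if (length(object@times) != length(object@counts))
    msg <- c(msg, "times and counts must have equal length")
  if (any(object@counts < 0)) msg <- c(msg, "counts must be non-negative")
  if (length(object@times) > 1) {
    dt <- diff(object@times)
    if (any(dt <= 0) ||
        max(abs(dt - object@channelWidth)) > 1e-6 * object@channelWidth)
      msg <- c(msg, "times must increase uniformly by channelWidth")
  }
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "DTOF", function(object) {
  cat(sprintf("DTOF at %.1f nm: %d channels x %.2f ps, Ntot = %.4g\n",
              object@wavelength, length(object@times), object@channelWidth,
              sum(object@counts)))
})

#' SimResult: output of one Monte Carlo run at one wavelength
#'
#' Per detected photon the exact time of flight and the partial pathlengths
#' in each layer are retained, so that any absorption perturbation can be
#' applied exactly afterwards (microscopic Beer-Lambert reweighting).
#' Transport itself is absorption-free; absorption enters as the
#' deterministic weight exp(-sum_j mua_j l_j) at analysis time.
#'
#' @slot photons numeric matrix with one row per detected photon and columns
#'   `t` (ps) and one partial pathlength per layer (mm).
#' @slot tallies named numeric: unit-weight bookkeeping of launched photons
#'   (detected, topOutside, side, bottom, expired).
#' @slot nLaunched number of launched photon packets.
#' @slot seed master RNG seed.
#' @slot wavelength nm.
#' @slot mua,musp optical properties used (per layer, mm^-1).
#' @slot refractiveIndex medium index (common to all layers).
#' @slot geometry the [Geometry-class] used.
#' @exportClass SimResult
setClass("SimResult",
  representation(photons = "matrix", tallies = "numeric",
                 nLaunched = "numeric", seed = "numeric",
                 wavelength = "numeric", mua = "numeric", musp = "numeric",
                 refractiveIndex = "numeric", geometry = "Geometry"))

setValidity("SimResult", function(object) {
  msg <- NULL
  if (nrow(object@photons) > 0 && any(object@photons < 0))
    msg <- c(msg, "photon records must be non-negative")
  if (abs(sum(object@tallies) - object@nLaunched) > 1e-9 * object@nLaunched)
    msg <- c(msg, "tallies must account for every launched photon")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "SimResult", function(object) {
  cat(sprintf("SimResult at %.1f nm: %d / %.4g photons detected (seed %d)\n",
              object@wavelength, nrow(object@photons), object@nLaunched,
              as.integer(object@seed)))
})

#' SensitivityMatrix: moment sensitivities to per-layer absorption changes
#'
#' Rows are the three DTOF moments (attenuation A, mean time of flight T,
#' variance V), columns the tissue layers.  The entries are the mean partial
#' pathlength MPP (mm), the mean-time-of-flight sensitivity factor MTSF
#' (ps mm) and the variance sensitivity factor VSF (ps^2 mm), signed such
#' that dA = sum_j MPP_j dmua_j, dT = sum_j MTSF_j dmua_j and
#' dV = sum_j VSF_j dmua_j (MTSF and VSF are therefore negative: increasing
#' absorption preferentially removes late photons).
#'
#' @slot factors 3 x nLayer numeric matrix.
#' @slot wavelength nm.
#' @exportClass SensitivityMatrix
setClass("SensitivityMatrix",
  representation(factors = "matrix", wavelength = "numeric"))

setValidity("SensitivityMatrix", function(object) {
  msg <- NULL
  if (nrow(object@factors) != 3)
    msg <- c(msg, "factors must have rows MPP, MTSF, VSF")
  if (any(!is.finite(object@factors))) msg <- c(msg, "factors must be finite")
  if (any(object@factors["MPP", ] < 0))
    msg <- c(msg, "MPP must be non-negative")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "SensitivityMatrix", function(object) {
  cat(sprintf("SensitivityMatrix at %.1f nm\n", object@wavelength))
  print(round(object@factors, 3))
})
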