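# Tissue model construction: layer composition -> wavelength-resolved
# optical properties.  Default composition follows the three-layer adult
# head model used throughout (scalp 4 mm / skull 7 mm / semi-infinite
# brain); scattering is the Mie power law mu_s' = a * lambda^-b.

#' Construct a tissue layer specification
#'
#' @param name layer label.
#' @param thickness mm (ignored when `semiInfinite`).
#' @param semiInfinite logical; the layer fills the rest of the slab.
#' @param cHbO2,cHb,cCCO,cCytB,cCytC concentrations, micromolar.
#' @param waterFraction,lipidFraction volume fractions, percent.
#' @param backgroundMua constant background absorption, mm^-1.
#' @param muaConstant when TRUE the layer absorption is `backgroundMua` at
#'   every wavelength (the skull convention).
#' @param scatterA,scatterB Mie power-law parameters (`scatterA` in mm^-1
#'   with wavelength in nm).
#' @param refractiveIndex,anisotropy optical constants.
#' @return a [LayerSpec-class].
#' @export
layerSpec <- function(name, thickness = 1, semiInfinite = FALSE,
                      cHbO2 = 0, cHb = 0, waterFraction = 0,
                      lipidFraction = 0, cCCO = 0, cCytB = 0, cCytC = 0,
                      backgroundMua = 0, muaConstant = FALSE,
                      scatterA = 2 * 800^1.4, scatterB = 1.4,
                      refractiveIndex = 1.4, anisotropy = 0) {
  new("LayerSpec", name = name, thickness = thickness,
      semiInfinite = semiInfinite, cHbO2 = cHbO2, cHb = cHb,
      waterFraction = waterFraction, lipidFraction = lipidFraction,
      cCCO = cCCO, cCytB = cCytB, cCytC = cCytC,
      backgroundMua = backgroundMua, muaConstant = muaConstant,
      scatterA = scatterA, scatterB = scatterB,
      refractiveIndex = refractiveIndex, anisotropy = anisotropy)
}

#' Hemoglobin concentrations from total hemoglobin and saturation
#'
#' @param tHb total hemoglobin, micromolar.
#' @param StO2 tissue oxygen saturation, percent.
#' @return named vector with elements `cHbO2`, `cHb`.
#' @export
hbFromSaturation <- function(tHb, StO2) {
  stopifnot(tHb >= 0, StO2 >= 0, StO2 <= 100)
  c(cHbO2 = tHb * StO2 / 100, cHb = tHb * (1 - StO2 / 100))
}

# Scattering power-law parameters anchored at 800 nm so that the NIR
# reduced scattering is ~2.0 (scalp), 1.8 (skull) and 2.2 (brain) mm^-1.
.scatterAnchor <- function(musp800, b) musp800 * 800^b

#' Default head-model layers
#'
#' The three-layer adult head model used as the package fixture: 4 mm scalp
#' (46/19 uM HbO2/Hb, 60% water, 13% lipid, 0.005 mm^-1 background), 7 mm
#' skull with constant absorption 0.015 mm^-1, and a semi-infinite brain
#' (56/24 uM HbO2/Hb i.e. StO2 70%, 80% water, 11.6% lipid, cytochromes
#' 8 / 2.37 / 1.36 uM).  Refractive index 1.4 throughout.
#'
#' @return list of three [LayerSpec-class] objects (scalp, skull, brain).
#' @export
defaultLayers <- function() {
  list(
    layerSpec("scalp", thickness = 4, cHbO2 = 46, cHb = 19,
              waterFraction = 60, lipidFraction = 13,
              backgroundMua = 0.005,
              scatterA = .scatterAnchor(2.0, 1.4), scatterB = 1.4),
    layerSpec("skull", thickness = 7, backgroundMua = 0.015,
              muaConstant = TRUE,
              scatterA = .scatterAnchor(1.8, 1.2), scatterB = 1.2),
    layerSpec("brain", semiInfinite = TRUE, thickness = 69,
              cHbO2 = 56, cHb = 24, waterFraction = 80,
              lipidFraction = 11.6, cCCO = 8, cCytB = 2.37, cCytC = 1.36,
              backgroundMua = 0,
              scatterA = .scatterAnchor(2.2, 1.6), scatterB = 1.6))
}

#' Build the absorption spectrum of one layer
#'
#' mu_a(lambda) = sum_k eps_k(lambda) C_k + background, where the sum runs
#' over the hemoglobins, the oxidised cytochromes (static absorption) and
#' the water/lipid volume fractions.  For a layer flagged `muaConstant`
#' (skull) the background value is returned at every wavelength.
#'
#' @param layer a [LayerSpec-class].
#' @param spectra named list of [SpectralCurve-class]; every constituent
#'   with a nonzero concentration must have a spectrum covering the grid.
#' @param wavelengths nm grid.
#' @return numeric vector of mu_a, mm^-1.
#' @export
buildAbsorption <- function(layer, spectra, wavelengths) {
  if (layer@muaConstant)
    return(rep(layer@backgroundMua, length(wavelengths)))
  comp <- c(HbO2 = layer@cHbO2, Hb = layer@cHb,
            CCO_oxidised = layer@cCCO, cytb_oxidised = layer@cCytB,
            cytc_oxidised = layer@cCytC,
            water = layer@waterFraction / 100,
            lipid = layer@lipidFraction / 100)
  mua <- rep(layer@backgroundMua, length(wavelengths))
  for (k in names(comp)) {
    if (comp[[k]] == 0) next
    if (is.null(spectra[[k]]))
      stop("constituent '", k, "' has nonzero concentration in layer '",
           layer@name, "' but no spectrum was supplied")
    mua <- mua + comp[[k]] * spectrumValues(spectra[[k]], wavelengths)
  }
  if (any(mua <= 0)) stop("built absorption must be positive")
  mua
}

#' Build the reduced scattering spectrum of one layer
#'
#' mu_s'(lambda) = a * lambda^-b with lambda in nm.
#'
#' @param layer a [LayerSpec-class].
#' @param wavelengths nm grid.
#' @return numeric vector of mu_s', mm^-1.
#' @export
buildScattering <- function(layer, wavelengths) {
  if (layer@scatterA <= 0) stop("scattering amplitude must be positive")
  if (layer@scatterB < 0) stop("scattering power must be non-negative")
  layer@scatterA * wavelengths^(-layer@scatterB)
}

#' Assemble a tissue model
#'
#' Builds the wavelength-resolved absorption and reduced scattering of all
#' layers.  The `convention` argument selects how molar extinction spectra
#' enter the absorption sum: `"decadic"` uses the base-10 values as
#' printed by compilations, `"natural"` multiplies them by ln(10).  The
#' same convention must be used for the Beer-Lambert unmixing step so that
#' the forward and inverse chains stay consistent (see the package
#' vignette for the discussion of this choice).
#'
#' @param layers list of [LayerSpec-class]; default [defaultLayers()].
#' @param wavelengths nm grid; default 650-950 nm in steps of 12.5 nm
#'   (25 wavelengths).
#' @param spectra named list of constituent spectra; defaults to the
#'   bundled tables in the requested convention.
#' @param convention `"decadic"` or `"natural"`.
#' @return a [TissueModel-class].
#' @export
tissueModel <- function(layers = defaultLayers(),
                        wavelengths = defaultWavelengthGrid(),
                        spectra = NULL,
                        convention = c("decadic", "natural")) {
  convention <- match.arg(convention)
  if (is.null(spectra)) spectra <- nirsSpectra(convention)
  mua <- t(vapply(layers, buildAbsorption, numeric(length(wavelengths)),
                  spectra = spectra, wavelengths = wavelengths))
  musp <- t(vapply(layers, buildScattering, numeric(length(wavelengths)),
                   wavelengths = wavelengths))
  rownames(mua) <- rownames(musp) <-
    vapply(layers, function(l) l@name, character(1))
  new("TissueModel", layers = layers, wavelengths = wavelengths,
      mua = mua, musp = musp, convention = convention)
}

#' Default simulation wavelength grid
#'
#' @return 650 to 950 nm in steps of 12.5 nm (25 wavelengths).
#' @export
defaultWavelengthGrid <- function() seq(650, 950, by = 12.5)

#' Default head model on the default grid
#'
#' @inheritParams tissueModel
#' @return a [TissueModel-class].
#' @export
defaultHeadModel <- function(convention = "decadic") {
  tissueModel(convention = convention)
}

#' @describeIn tissueModel accessor: wavelength grid, nm.
#' @param model a [TissueModel-class].
#' @export
modelWavelengths <- function(model) model@wavelengths

#' @describeIn tissueModel accessor: absorption matrix (layer x wavelength).
#' @export
absorptionCoeff <- function(model) model@mua

#' @describeIn tissueModel accessor: reduced scattering matrix.
#' @export
scatteringCoeff <- function(model) model@musp

#' @describeIn tissueModel accessor: layer thicknesses, mm (the final,
#'   semi-infinite layer is truncated by the slab depth at simulation time).
#' @export
layerThicknesses <- function(model) {
  vapply(model@layers, function(l) l@thickness, numeric(1))
}

.layerToList <- function(l) {
  list(name = l@name, thickness_mm = l@thickness,
       semi_infinite = l@semiInfinite, c_hbo2_uM = l@cHbO2, c_hb_uM = l@cHb,
       water_percent = l@waterFraction, lipid_percent = l@lipidFraction,
       c_cco_uM = l@cCCO, c_cytb_uM = l@cCytB, c_cytc_uM = l@cCytC,
       background_mua_mm1 = l@backgroundMua, mua_constant = l@muaConstant,
       scatter_a = l@scatterA, scatter_b = l@scatterB,
       refractive_index = l@refractiveIndex, anisotropy_g = l@anisotropy)
}

.layerFromList <- function(x) {
  layerSpec(x$name, thickness = x$thickness_mm,
            semiInfinite = isTRUE(x$semi_infinite), cHbO2 = x$c_hbo2_uM,
            cHb = x$c_hb_uM, waterFraction = x$water_percent,
            lipidFraction = x$lipid_percent, cCCO = x$c_cco_uM,
            cCytB = x$c_cytb_uM, cCytC = x$c_cytc_uM,
            backgroundMua = x$background_mua_mm1,
            muaConstant = isTRUE(x$mua_constant), scatterA = x$scatter_a,
            scatterB = x$scatter_b, refractiveIndex = x$refractive_index,
            anisotropy = x$anisotropy_g)
}

#' Serialize a tissue model to JSON
#'
#' The document mirrors the layer-composition table field-for-field plus
#' the wavelength grid and extinction convention; [tissueModelFromJSON()]
#' reads it back and rebuilds the optical-property matrices.
#'
#' @param model a [TissueModel-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
tissueModelToJSON <- function(model, path) {
  doc <- list(convention = model@convention,
              wavelengths_nm = model@wavelengths,
              layers = lapply(model@layers, .layerToList))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname tissueModelToJSON
#' @export
tissueModelFromJSON <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  layers <- lapply(doc$layers, .layerFromList)
  tissueModel(layers = layers, wavelengths = as.numeric(doc$wavelengths_nm),
              convention = doc$convention)
}
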