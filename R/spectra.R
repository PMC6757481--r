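#' Interpolate a tabulated curve
#'
#' Deterministic interpolation of a two-column table onto a query grid.
#' `"linear"` uses piecewise-linear interpolation, `"spline"` a cubic
#' spline with Forsythe-Malcolm-Moler end conditions (the behaviour of the
#' classic numerical `spline` routines; exact for cubic polynomials).
#' Queries outside the table span are an error: no extrapolation is ever
#' performed.
#'
#' @param x,y table nodes (x strictly increasing).
#' @param xout query grid.
#' @param method `"linear"` or `"spline"`.
#' @return numeric vector of interpolated values on `xout`.
#' @export
interpolateCurve <- function(x, y, xout, method = c("spline", "linear")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (any(diff(x) <= 0)) stop("table nodes must be strictly increasing")
  if (any(xout < min(x) - 1e-9) || any(xout > max(x) + 1e-9))
    stop(sprintf("query outside table span [%g, %g]: extrapolation refused",
                 min(x), max(x)))
  if (method == "linear") {
    approx(x, y, xout = xout, rule = 1)$y
  } else {
    spline(x, y, xout = xout, method = "fmm")$y
  }
}

.parseHeaderField <- function(lines, field) {
  hit <- grep(sprintf("^#\\s*%s:", field), lines, value = TRUE)
  if (length(hit) == 0) return(NA_character_)
  trimws(sub(sprintf("^#\\s*%s:", field), "", hit[1]))
}

#' Read a bundled two-column spectral table
#'
#' Parses a plain-text table whose header comments declare the species, the
#' units and the logarithm convention of the values.  Molar extinction
#' values given in mM^-1 cm^-1 are converted to mm^-1 per micromolar;
#' absolute absorption (`mua`) and responsivity tables are kept as read.
#'
#' @param path file path.
#' @return a [SpectralCurve-class].
#' @export
readSpectralTable <- function(path) {
  if (!file.exists(path)) stop("spectral table not found: ", path)
  lines <- readLines(path)
  species <- .parseHeaderField(lines, "species")
  units <- .parseHeaderField(lines, "units")
  convention <- .parseHeaderField(lines, "convention")
  if (is.na(convention)) stop("table must declare its convention: ", path)
  tab <- read.table(text = lines[!grepl("^#", lines) & nzchar(lines)],
                    col.names = c("wavelength", "value"))
  scale <- switch(units,
    "mM^-1 cm^-1" = 1e-4,   # -> mm^-1 uM^-1
    "uM^-1 mm^-1" = 1,
    "mm^-1" = 1,
    "relative" = 1,
    stop("unknown units '", units, "' in ", path))
  new("SpectralCurve", species = species,
      wavelengths = tab$wavelength, values = tab$value * scale,
      convention = convention)
}

.extdata <- function(file) {
  system.file("extdata", file, package = "trnirs", mustWork = TRUE)
}

#' Convert a spectral curve between logarithm conventions
#'
#' Molar extinction spectra tabulated in the decadic (base-10) convention
#' are multiplied by ln(10) to obtain the natural-log convention required
#' when attenuation changes are defined through natural logarithms.
#' Absolute absorption (`mua`) and responsivity curves are convention-free
#' and returned unchanged.
#'
#' @param curve a [SpectralCurve-class].
#' @param convention `"decadic"` or `"natural"`.
#' @return a [SpectralCurve-class] in the requested convention.
#' @export
asConvention <- function(curve, convention = c("decadic", "natural")) {
  convention <- match.arg(convention)
  if (curve@convention %in% c("mua", "responsivity")) return(curve)
  if (curve@convention == convention) return(curve)
  factor <- if (convention == "natural") log(10) else 1 / log(10)
  new("SpectralCurve", species = curve@species,
      wavelengths = curve@wavelengths, values = curve@values * factor,
      convention = convention)
}

#' Bundled chromophore spectra
#'
#' Loads the bundled constituent spectra: specific extinction of HbO2, Hb
#' and the oxidised-minus-reduced difference spectrum of
#' cytochrome-c-oxidase (oxCCO), absolute oxidised cytochrome spectra used
#' for static absorption, and water and lipid absorption.  The bundled
#' tables are synthetic digitizations of published compilations (see the
#' files under `extdata/`); they are accurate at roughly the percent level.
#'
#' @param convention extinction convention for the molar species;
#'   `"decadic"` (default, base-10 values as compilations print them) or
#'   `"natural"` (multiplied by ln(10)).
#' @return named list of [SpectralCurve-class] objects with elements
#'   `HbO2`, `Hb`, `oxCCO`, `CCO_oxidised`, `cytb_oxidised`,
#'   `cytc_oxidised`, `water`, `lipid`.
#' @export
nirsSpectra <- function(convention = c("decadic", "natural")) {
  convention <- match.arg(convention)
  files <- c(HbO2 = "extinction_hbo2_synthetic.tsv",
             Hb = "extinction_hb_synthetic.tsv",
             oxCCO = "extinction_oxcco_diff_synthetic.tsv",
             CCO_oxidised = "extinction_cco_oxidised_synthetic.tsv",
             cytb_oxidised = "extinction_cytb_oxidised_synthetic.tsv",
             cytc_oxidised = "extinction_cytc_oxidised_synthetic.tsv",
             water = "absorption_water_synthetic.tsv",
             lipid = "absorption_lipid_synthetic.tsv")
  lapply(files, function(f) asConvention(readSpectralTable(.extdata(f)),
                                         convention))
}

#' Bundled multialkali-cathode responsivity curve
#'
#' Relative spectral detection efficiency of a multialkali-cathode
#' photon-counting detector over 650-950 nm (synthetic digitization,
#' normalised to 1 at 650 nm; declines monotonically with wavelength).
#'
#' @return a [SpectralCurve-class] with convention `"responsivity"`.
#' @export
multialkaliResponsivity <- function() {
  readSpectralTable(.extdata("responsivity_multialkali_synthetic.tsv"))
}

#' Evaluate a spectral curve on a wavelength grid
#'
#' @param curve a [SpectralCurve-class].
#' @param wavelengths nm grid (within the table span).
#' @param method interpolation method, see [interpolateCurve()].
#' @return numeric vector.
#' @export
spectrumValues <- function(curve, wavelengths, method = "spline") {
  interpolateCurve(curve@wavelengths, curve@values, wavelengths,
                   method = method)
}

#' Extinction matrix for a chromophore set
#'
#' Builds the (wavelength x chromophore) matrix E of specific extinction
#' coefficients used by the Beer-Lambert unmixing step, in the convention
#' the supplied curves carry.
#'
#' @param spectra named list of [SpectralCurve-class] (e.g. [nirsSpectra()]).
#' @param wavelengths nm grid.
#' @param chromophores character vector of names to include, in column
#'   order (e.g. `c("HbO2", "Hb", "oxCCO")`).
#' @return numeric matrix, mm^-1 uM^-1, with chromophore column names.
#' @export
extinctionMatrix <- function(spectra, wavelengths,
                             chromophores = c("HbO2", "Hb", "oxCCO")) {
  missing <- setdiff(chromophores, names(spectra))
  if (length(missing) > 0)
    stop("no spectrum for chromophore(s): ", paste(missing, collapse = ", "))
  E <- vapply(chromophores,
              function(k) spectrumValues(spectra[[k]], wavelengths),
              numeric(length(wavelengths)))
  E <- matrix(E, nrow = length(wavelengths),
              dimnames = list(NULL, chromophores))
  E
}
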