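# Configuration, validation/logging and file-format plumbing.
# Units policy: lengths mm, time ps, concentrations uM, wavelengths nm,
# mua/mus' mm^-1 everywhere inside the package; converters act only at the
# I/O boundary (a config may declare `length_unit: "cm"`).

#' Default run configuration
#'
#' The packaged fixture: the default three-layer head model, the default
#' ring-detector geometry, the 25-wavelength grid, a photon budget of
#' 1.5e6 and a spectrally uniform detector.
#'
#' @param nPhotons photon packets per wavelength.
#' @param seed master RNG seed.
#' @return a named list (class `trnirsConfig`).
#' @export
defaultRunConfig <- function(nPhotons = 1e6, seed = 1) {
  structure(list(
    length_unit = "mm",
    model = list(convention = "decadic",
                 wavelengths_nm = defaultWavelengthGrid(),
                 layers = lapply(defaultLayers(), .layerToList)),
    geometry = list(slab_xy_mm = 120, slab_z_mm = 80,
                    ring_inner_mm = 28.5, ring_outer_mm = 31.5,
                    n_time_channels = 128, channel_width_ps = 19.5,
                    ambient_index = 1.0),
    photons_per_wavelength = nPhotons,
    seed = seed,
    responsivity = "uniform",
    budget = 1.5e6,
    scan_mode = "consecutive16"),
    class = "trnirsConfig")
}

#' Read / write a run configuration
#'
#' @param path JSON file.
#' @param config a configuration list.
#' @return `readRunConfig` returns the parsed (unvalidated) configuration;
#'   `writeRunConfig` returns `path` invisibly.
#' @export
readRunConfig <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  class(cfg) <- "trnirsConfig"
  cfg
}

#' @rdname readRunConfig
#' @export
writeRunConfig <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Hash of a configuration
#'
#' MD5 digest of the canonical JSON serialisation; embedded in result
#' files so a run can be reproduced from its own metadata.
#'
#' @param config a configuration list.
#' @return character MD5 string.
#' @export
configHash <- function(config) {
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA)
  unname(tools::md5sum(path))
}

.requireFields <- function(x, fields, where) {
  missing <- setdiff(fields, names(x))
  if (length(missing) > 0)
    stop("configuration invalid: missing field(s) ",
         paste0(where, "$", missing, collapse = ", "))
}

#' Validate and normalise a run configuration
#'
#' Checks the configuration document, normalises units to the internal
#' policy (mm/ps/uM/nm), resolves the responsivity table, and accumulates
#' a structured key-value log of every normalisation and derived quantity.
#'
#' @param config a configuration list (see [defaultRunConfig()]).
#' @return list with elements `config` (normalised), `model` (the built
#'   [TissueModel-class]), `geometry` ([Geometry-class]), `responsivity`
#'   (`NULL` or a [SpectralCurve-class]) and `log` (data.frame of
#'   key-value entries, including the config hash and seed).
#' @export
validateRunConfig <- function(config) {
  logs <- list()
  addLog <- function(key, value)
    logs[[length(logs) + 1]] <<- data.frame(key = key,
                                            value = as.character(value))
  .requireFields(config, c("model", "geometry", "photons_per_wavelength",
                           "seed", "responsivity", "budget"), "config")
  unit <- if (is.null(config$length_unit)) "mm" else config$length_unit
  scale <- switch(unit, mm = 1, cm = 10,
                  stop("configuration invalid: unknown length_unit '",
                       unit, "'"))
  if (scale != 1) {
    for (i in seq_along(config$model$layers))
      config$model$layers[[i]]$thickness_mm <-
        config$model$layers[[i]]$thickness_mm * scale
    g <- config$geometry
    for (f in c("slab_xy_mm", "slab_z_mm", "ring_inner_mm", "ring_outer_mm"))
      config$geometry[[f]] <- g[[f]] * scale
    addLog("unit_conversion", sprintf("lengths converted %s -> mm", unit))
    config$length_unit <- "mm"
  }
  .requireFields(config$geometry,
                 c("slab_xy_mm", "slab_z_mm", "ring_inner_mm",
                   "ring_outer_mm", "n_time_channels", "channel_width_ps",
                   "ambient_index"), "geometry")
  geometry <- defaultGeometry(slabXY = config$geometry$slab_xy_mm,
                              slabZ = config$geometry$slab_z_mm,
                              ringInner = config$geometry$ring_inner_mm,
                              ringOuter = config$geometry$ring_outer_mm,
                              nChannels = config$geometry$n_time_channels,
                              channelWidth = config$geometry$channel_width_ps,
                              ambientIndex = config$geometry$ambient_index)
  layers <- lapply(config$model$layers, .layerFromList)
  model <- tissueModel(layers = layers,
                       wavelengths = as.numeric(config$model$wavelengths_nm),
                       convention = config$model$convention)
  responsivity <- NULL
  if (!identical(config$responsivity, "uniform")) {
    if (identical(config$responsivity, "multialkali")) {
      responsivity <- multialkaliResponsivity()
    } else {
      if (!file.exists(config$responsivity))
        stop("configuration invalid: responsivity file not found: ",
             config$responsivity)
      responsivity <- readSpectralTable(config$responsivity)
    }
  }
  addLog("config_hash", configHash(config))
  addLog("seed", config$seed)
  addLog("photons_per_wavelength", config$photons_per_wavelength)
  addLog("budget", config$budget)
  addLog("n_wavelengths", length(model@wavelengths))
  for (i in seq_along(model@layers))
    addLog(sprintf("mua_%s_at_%gnm", model@layers[[i]]@name,
                   model@wavelengths[1]),
           sprintf("%.6g", model@mua[i, 1]))
  list(config = config, model = model, geometry = geometry,
       responsivity = responsivity, log = do.call(rbind, logs))
}

#' Export DTOFs as a flat CSV table
#'
#' Schema: `wavelength_nm, channel_index, time_ps, counts`.
#'
#' @param dtofs list of [DTOF-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeDtofCSV <- function(dtofs, path) {
  tab <- do.call(rbind, lapply(dtofs, function(d) {
    data.frame(wavelength_nm = d@wavelength,
               channel_index = seq_along(d@times) - 1L,
               time_ps = d@times, counts = d@counts)
  }))
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeDtofCSV
#' @return `readDtofCSV` returns a list of [DTOF-class].
#' @export
readDtofCSV <- function(path) {
  tab <- read.csv(path)
  lapply(split(tab, tab$wavelength_nm), function(d) {
    d <- d[order(d$channel_index), ]
    new("DTOF", wavelength = d$wavelength_nm[1], times = d$time_ps,
        counts = d$counts, channelWidth = diff(d$time_ps[1:2]))
  })
}

#' Export a wavelength scan as CSV
#'
#' Schema: `band_start_nm, band_end_nm, n_wavelengths, layer, chromophore,
#' sigma_dC_uM, responsivity, budget`.
#'
#' @param scan a scan data.frame from [scanConsecutive16()] or
#'   [scanEvenSpread()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeScanCSV <- function(scan, path) {
  out <- data.frame(band_start_nm = scan$band_start_nm,
                    band_end_nm = scan$band_end_nm,
                    n_wavelengths = scan$n_wavelengths,
                    layer = scan$layer, chromophore = scan$chromophore,
                    sigma_dC_uM = scan$sigma_uM,
                    responsivity = scan$responsivity,
                    budget = scan$budget)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
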