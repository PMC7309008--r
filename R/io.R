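#' Read a two-column spectrum CSV
#'
#' The spectrometer-export dialect: two numeric columns (wavelength in nm,
#' relative value), comma-separated, with an optional single header line.
#' Rows are sorted ascending on load; duplicate wavelengths are averaged
#' with a warning.
#'
#' @param path Path to the CSV file.
#' @param kind Spectrum kind to assign (default `"emission"`).
#' @param label Label; defaults to the file name.
#' @return An [ox_spectrum].
#' @export
read_spectrum_csv <- function(path, kind = "emission", label = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty spectrum file: ", path)
  parse_row <- function(ln) suppressWarnings(
    as.numeric(strsplit(ln, ",")[[1]]))
  first <- parse_row(lines[1])
  has_header <- anyNA(first) || length(first) < 2L
  data_lines <- if (has_header) lines[-1] else lines
  if (length(data_lines) < 2L)
    stop("spectrum file must contain at least two data rows: ", path)
  rows <- lapply(data_lines, parse_row)
  bad <- which(vapply(rows, function(r) anyNA(r[1:2]) || length(r) < 2L,
                      logical(1)))
  if (length(bad))
    stop(sprintf("non-numeric spectrum row at line %d of %s",
                 bad[1] + as.integer(has_header), path))
  w <- vapply(rows, `[`, numeric(1), 1L)
  v <- vapply(rows, `[`, numeric(1), 2L)
  o <- order(w)
  w <- w[o]; v <- v[o]
  if (anyDuplicated(w)) {
    warning("duplicate wavelengths averaged in ", path)
    v <- as.numeric(tapply(v, w, mean))
    w <- sort(unique(w))
  }
  ox_spectrum(w, v, kind = kind,
              label = if (is.null(label)) basename(path) else label)
}

#' Write a spectrum as a two-column CSV
#'
#' @param s An [ox_spectrum].
#' @param path Output path.
#' @param header Write the `wavelength_nm,value` header line? (default
#'   `TRUE`)
#' @param digits Significant digits written (default 15, lossless to
#'   double precision for round trips).
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(s, path, header = TRUE, digits = 15) {
  stopifnot(inherits(s, "ox_spectrum"))
  lines <- paste(format(s$wavelength, digits = digits, trim = TRUE,
                        scientific = FALSE),
                 format(s$value, digits = digits, trim = TRUE),
                 sep = ",")
  if (header) lines <- c("wavelength_nm,value", lines)
  writeLines(lines, path)
  invisible(path)
}

#' Read an extinction table CSV
#'
#' Three named columns, header required: `wavelength_nm`, `eps_hbo2`,
#' `eps_hb` (L mol^-1 cm^-1).
#'
#' @param path Path to the CSV file.
#' @param source_tag Provenance tag; defaults to the file name.
#' @return An [ox_chromophore_table][chromophore_table].
#' @export
read_extinction_csv <- function(path, source_tag = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("wavelength_nm", "eps_hbo2", "eps_hb")
  if (!all(need %in% names(df)))
    stop("extinction CSV must have a header with columns ",
         paste(need, collapse = ", "))
  o <- order(df$wavelength_nm)
  chromophore_table(df$wavelength_nm[o], df$eps_hbo2[o], df$eps_hb[o],
                    source_tag = if (is.null(source_tag)) basename(path)
                                 else source_tag)
}

#' Write an extinction table CSV
#'
#' @param table An [ox_chromophore_table][chromophore_table].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_extinction_csv <- function(table, path) {
  stopifnot(inherits(table, "ox_chromophore_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Load a component registry
#'
#' Reads a YAML registry of candidate light sources for pulse oximetry,
#' each entry carrying datasheet parameters (dominant wavelength, peak
#' wavelength, FWHM — any of which a datasheet may omit) and measured
#' parameters (peak wavelength and FWHM from a spectrometer
#' characterization). The bundled registry covers a selection of red, IR,
#' dual- and triple-wavelength emitters spanning roughly 525-950 nm,
#' including two commercial double-wavelength probes for which only
#' measured values are available.
#'
#' @param path Path to a registry YAML; default the bundled registry.
#' @return An object of class `ox_registry`.
#' @export
load_registry <- function(path = system.file("extdata", "components.yaml",
                                             package = "oxishift")) {
  if (!nzchar(path) || !file.exists(path))
    stop("no such registry file: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$components))
    stop("registry must contain a top-level `components` list")
  for (comp in cfg$components) {
    if (is.null(comp$name)) stop("registry entry without a name")
    for (band in comp$bands) {
      ds <- band$datasheet
      ms <- band$measured
      ds_ok <- !is.null(ds) &&
        (!is.null(ds$lambda_dom) || !is.null(ds$lambda_peak)) &&
        !is.null(ds$fwhm)
      ms_ok <- !is.null(ms) && !is.null(ms$lambda_peak) &&
        !is.null(ms$fwhm)
      if (!ds_ok && !ms_ok)
        stop(sprintf(
          "registry entry '%s' (%s band) has neither usable datasheet nor measured parameters",
          comp$name, band$channel))
    }
  }
  structure(list(components = cfg$components,
                 path = path),
            class = "ox_registry")
}

#' @export
print.ox_registry <- function(x, ...) {
  cat(sprintf("<component registry: %d components>\n",
              length(x$components)))
  for (comp in x$components)
    cat(sprintf("  %-12s %-9s %s\n", comp$name, comp$manufacturer,
                paste(vapply(comp$bands, `[[`, character(1), "channel"),
                      collapse = "+")))
  invisible(x)
}

#' Registry contents as a flat table
#'
#' One row per emitter band, mirroring a datasheet comparison table:
#' datasheet dominant wavelength, peak wavelength and FWHM (NA where the
#' datasheet omits the value) next to the measured peak wavelength and
#' FWHM.
#'
#' @param registry An [ox_registry][load_registry].
#' @return A data.frame.
#' @export
registry_table <- function(registry) {
  stopifnot(inherits(registry, "ox_registry"))
  num_or_na <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  rows <- lapply(registry$components, function(comp) {
    do.call(rbind, lapply(comp$bands, function(band) {
      data.frame(name = comp$name, manufacturer = comp$manufacturer,
                 package = comp$package, channel = band$channel,
                 ds_lambda_dom = num_or_na(band$datasheet$lambda_dom),
                 ds_lambda_peak = num_or_na(band$datasheet$lambda_peak),
                 ds_fwhm = num_or_na(band$datasheet$fwhm),
                 meas_lambda_peak = num_or_na(band$measured$lambda_peak),
                 meas_fwhm = num_or_na(band$measured$fwhm))
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build a light source from a registry entry
#'
#' Measured parameters are preferred by default (they describe the part on
#' the bench); with `prefer = "datasheet"` the datasheet parameters are
#' used, taking the dominant wavelength over the peak wavelength when both
#' are quoted, since the dominant (centroid) wavelength is the headline
#' optical feature and the better single-center summary of a skewed line.
#'
#' @param registry An [ox_registry][load_registry].
#' @param name Component name.
#' @param channel Band channel (`"red"`, `"ir"`, `"green"`); defaults to
#'   the entry's only band.
#' @param prefer `"measured"` (default) or `"datasheet"`.
#' @return An [ox_light_source][light_source].
#' @export
registry_source <- function(registry, name, channel = NULL,
                            prefer = c("measured", "datasheet")) {
  stopifnot(inherits(registry, "ox_registry"))
  prefer <- match.arg(prefer)
  names_all <- vapply(registry$components, `[[`, character(1), "name")
  idx <- match(name, names_all)
  if (is.na(idx))
    stop(sprintf("unknown component '%s'; registry has: %s", name,
                 paste(names_all, collapse = ", ")))
  comp <- registry$components[[idx]]
  bands <- comp$bands
  if (is.null(channel)) {
    if (length(bands) > 1L)
      stop(sprintf("component '%s' has bands %s; specify `channel`",
                   name, paste(vapply(bands, `[[`, character(1),
                                      "channel"), collapse = ", ")))
    band <- bands[[1]]
  } else {
    chs <- vapply(bands, `[[`, character(1), "channel")
    j <- match(channel, chs)
    if (is.na(j))
      stop(sprintf("component '%s' has no '%s' band", name, channel))
    band <- bands[[j]]
  }
  pick <- function(src) {
    if (identical(src, "measured")) {
      ms <- band$measured
      if (is.null(ms$lambda_peak) || is.null(ms$fwhm)) return(NULL)
      c(center = as.numeric(ms$lambda_peak), fwhm = as.numeric(ms$fwhm))
    } else {
      ds <- band$datasheet
      ctr <- if (!is.null(ds$lambda_dom)) ds$lambda_dom else ds$lambda_peak
      if (is.null(ctr) || is.null(ds$fwhm)) return(NULL)
      c(center = as.numeric(ctr), fwhm = as.numeric(ds$fwhm))
    }
  }
  p <- pick(prefer)
  if (is.null(p)) {
    other <- setdiff(c("measured", "datasheet"), prefer)
    p <- pick(other)
    if (is.null(p))
      stop(sprintf("component '%s' has no usable (center, fwhm) pair",
                   name))
  }
  drive <- if (!is.null(comp$drive_current)) comp$drive_current else 20
  light_source(paste0(name, if (!is.null(channel)) paste0(":", channel)),
               gaussian_band(p[["center"]], p[["fwhm"]]),
               drive_current = drive)
}

#' Red/IR pairs defined by the registry
#'
#' Builds the oximetry-relevant red+IR pairings: dual- and
#' triple-wavelength components are paired internally, single-wavelength
#' red and IR emitters are paired as named in the registry's `pairs`
#' section, and the generic 660/940 pair is appended for reference.
#'
#' @param registry An [ox_registry][load_registry].
#' @param detector Shared [ox_photodetector][photodetector].
#' @param prefer Parameter preference passed to [registry_source()].
#' @param include_generic Append the generic 660/940 nm pair?
#' @return Named list of [ox_pair][source_detector_pair] objects.
#' @export
registry_pairs <- function(registry,
                           detector = synthetic_detector("flat"),
                           prefer = c("measured", "datasheet"),
                           include_generic = TRUE) {
  stopifnot(inherits(registry, "ox_registry"))
  prefer <- match.arg(prefer)
  pairs <- list()
  for (pr in .default_pairs) {
    p <- tryCatch(source_detector_pair(
      registry_source(registry, pr$red, pr$red_channel, prefer),
      registry_source(registry, pr$ir, pr$ir_channel, prefer),
      detector, label = pr$label), error = function(e) NULL)
    if (!is.null(p)) pairs[[pr$label]] <- p
  }
  if (include_generic)
    pairs[["generic"]] <- generic_pair(detector)
  pairs
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Red/IR pairings used for shift overviews: the typical red+IR pair, the
# internal pairs of the dual- and triple-wavelength components, and the
# two commercial probes.
.default_pairs <- list(
  list(label = "typical", red = "LHQ974", red_channel = NULL,
       ir = "SFH4248", ir_channel = NULL),
  list(label = "VSMD66694", red = "VSMD66694", red_channel = "red",
       ir = "VSMD66694", ir_channel = "ir"),
  list(label = "SMT660/890", red = "SMT660/890", red_channel = "red",
       ir = "SMT660/890", ir_channel = "ir"),
  list(label = "SFH7050", red = "SFH7050", red_channel = "red",
       ir = "SFH7050", ir_channel = "ir"),
  list(label = "LED#1", red = "LED #1", red_channel = "red",
       ir = "LED #1", ir_channel = "ir"),
  list(label = "LED#2", red = "LED #2", red_channel = "red",
       ir = "LED #2", ir_channel = "ir"))
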