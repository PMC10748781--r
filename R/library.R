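#' Metabolite signal model entry
#'
#' A metabolite (or unknown interfering signal) is modelled as a sum of
#' Lorentzian components. One reporter position is selected per entry: the
#' apex height there, per 1 mM at nominal linewidth, is the entry's unit
#' response and drives quantification. Linewidths are stored in Hz so that
#' the model transfers across field strengths; they are converted to ppm
#' through the library frequency at render time.
#'
#' @param name unique entry name.
#' @param components data frame with columns `center_ppm`, `rel_height`
#'   (> 0, apex intensity at unit concentration), `fwhm_hz` (> 0).
#' @param reporter_center_ppm nominal reporter position; default: the centre
#'   of the tallest component.
#' @param window_halfwidth_ppm peak-picking half window (default 0.01 ppm).
#' @param role `"target"` (quantified and reported) or `"interferent"`
#'   (solved for, suppressed from reports).
#' @param unit_response model intensity at the reporter apex per 1 mM;
#'   computed from the components when `NULL`. Must agree with the rendered
#'   model to within 0.1%.
#' @param frequency_mhz frequency used to validate/compute `unit_response`.
#' @return list of class `metabolite_entry`.
#' @export
metabolite_entry <- function(name, components, reporter_center_ppm = NULL,
                             window_halfwidth_ppm = 0.01,
                             role = c("target", "interferent"),
                             unit_response = NULL, frequency_mhz = 600) {
  role <- match.arg(role)
  components <- as.data.frame(components)
  need <- c("center_ppm", "rel_height", "fwhm_hz")
  if (!all(need %in% names(components)))
    stop(sprintf("entry '%s': components need columns %s",
                 name, paste(need, collapse = ", ")))
  if (nrow(components) < 1L) stop(sprintf("entry '%s': no components", name))
  if (any(components$rel_height <= 0) || any(components$fwhm_hz <= 0))
    stop(sprintf("entry '%s': rel_height and fwhm_hz must be > 0", name))
  if (is.null(reporter_center_ppm))
    reporter_center_ppm <- components$center_ppm[which.max(components$rel_height)]
  span <- range(components$center_ppm)
  if (reporter_center_ppm < span[1] - 0.05 || reporter_center_ppm > span[2] + 0.05)
    stop(sprintf("entry '%s': reporter centre %.4f outside component span",
                 name, reporter_center_ppm))
  if (window_halfwidth_ppm <= 0) stop("`window_halfwidth_ppm` must be > 0")

  e <- structure(list(name = as.character(name), role = role,
                      components = components,
                      reporter_center_ppm = reporter_center_ppm,
                      window_halfwidth_ppm = window_halfwidth_ppm,
                      unit_response = unit_response),
                 class = "metabolite_entry")
  ur <- entry_model_value(e, reporter_center_ppm, frequency_mhz)
  if (is.null(unit_response)) {
    e$unit_response <- ur
  } else {
    if (abs(unit_response - ur) > 1e-3 * abs(ur))
      stop(sprintf(
        "entry '%s': unit_response %.6g inconsistent with components (expected %.6g)",
        name, unit_response, ur))
  }
  e
}

# Closed-form Lorentzian-sum model value of one entry at arbitrary ppm.
# gamma_j = (fwhm_hz_j * fwhm_scale / frequency_mhz) / 2  [ppm]
entry_model_value <- function(entry, ppm, frequency_mhz,
                              offset_ppm = 0, fwhm_scale = 1) {
  val <- numeric(length(ppm))
  for (j in seq_len(nrow(entry$components))) {
    cj <- entry$components[j, ]
    gam <- (cj$fwhm_hz * fwhm_scale / frequency_mhz) / 2
    val <- val + cj$rel_height * gam^2 /
      ((ppm - cj$center_ppm - offset_ppm)^2 + gam^2)
  }
  val
}

#' Metabolite signal library
#'
#' A set of uniquely named entries (targets and interferents) plus exactly
#' one internal-standard entry of known concentration (a singlet near 0 ppm,
#' 0.29 mM by default) used for absolute calibration. Reporter windows of
#' distinct entries may overlap; the interference solve accounts for that.
#'
#' @param entries list of [metabolite_entry()] objects.
#' @param internal_standard a [metabolite_entry()] for the reference singlet.
#' @param known_concentration_mM internal-standard concentration (default 0.29).
#' @param frequency_mhz spectrometer frequency in MHz (default 600).
#' @return list of class `nmr_library`.
#' @export
nmr_library <- function(entries, internal_standard,
                        known_concentration_mM = 0.29, frequency_mhz = 600) {
  if (!length(entries)) stop("library needs at least one entry")
  nms <- vapply(entries, `[[`, character(1), "name")
  if (anyDuplicated(nms))
    stop(sprintf("duplicate entry name(s): %s",
                 paste(unique(nms[duplicated(nms)]), collapse = ", ")))
  if (!inherits(internal_standard, "metabolite_entry"))
    stop("`internal_standard` must be a metabolite_entry")
  if (internal_standard$name %in% nms)
    stop("internal standard name collides with an entry name")
  if (known_concentration_mM <= 0) stop("`known_concentration_mM` must be > 0")
  names(entries) <- nms
  structure(list(entries = entries, frequency_mhz = frequency_mhz,
                 internal_standard = internal_standard,
                 known_concentration_mM = known_concentration_mM),
            class = "nmr_library")
}

#' @export
print.nmr_library <- function(x, ...) {
  roles <- vapply(x$entries, `[[`, character(1), "role")
  cat(sprintf(
    "<nmr_library> %d target(s), %d interferent(s), IS '%s' @ %g mM, %g MHz\n",
    sum(roles == "target"), sum(roles == "interferent"),
    x$internal_standard$name, x$known_concentration_mM, x$frequency_mhz))
  invisible(x)
}

#' Names of library entries by role
#' @param library an `nmr_library`.
#' @param role `"target"`, `"interferent"`, or `"all"`.
#' @return character vector of names (internal standard excluded).
#' @export
library_names <- function(library, role = c("all", "target", "interferent")) {
  role <- match.arg(role)
  roles <- vapply(library$entries, `[[`, character(1), "role")
  if (role == "all") names(library$entries) else names(library$entries)[roles == role]
}

#' Render one library entry onto an axis
#'
#' Intensity at each bin centre is `concentration` times the closed-form
#' Lorentzian-sum model; the apex of an isolated component at 1 mM equals
#' its `rel_height`.
#'
#' @param entry a [metabolite_entry()].
#' @param axis an `nmr_axis`.
#' @param concentration_mM concentration (>= 0).
#' @param shift_offset_ppm rigid shift applied to the whole entry.
#' @param fwhm_scale multiplicative linewidth distortion (default 1).
#' @param frequency_mhz conversion frequency; default: the axis frequency.
#' @return an `nmr_spectrum`.
#' @export
render_entry <- function(entry, axis, concentration_mM,
                         shift_offset_ppm = 0, fwhm_scale = 1,
                         frequency_mhz = axis$frequency_mhz) {
  stopifnot(inherits(entry, "metabolite_entry"), inherits(axis, "nmr_axis"))
  if (concentration_mM < 0) stop("`concentration_mM` must be >= 0")
  if (fwhm_scale <= 0) stop("`fwhm_scale` must be > 0")
  centers <- entry$components$center_ppm + shift_offset_ppm
  inside <- vapply(centers, function(p)
    any(axis$segments$start_ppm <= p & p < axis$segments$end_ppm), logical(1))
  if (!any(inside))
    warning(sprintf("entry '%s': all components outside the axis", entry$name))
  vals <- concentration_mM *
    entry_model_value(entry, bin_centers(axis), frequency_mhz,
                      offset_ppm = shift_offset_ppm, fwhm_scale = fwhm_scale)
  nmr_spectrum(axis, vals, label = entry$name)
}

#' Render a mixture of library entries
#'
#' Elementwise sum of [render_entry()] over the named concentrations;
#' entries not named get concentration 0. The internal standard is rendered
#' when its name appears in `concentrations`.
#'
#' @param library an `nmr_library`.
#' @param axis an `nmr_axis`.
#' @param concentrations named numeric vector, mM per entry name.
#' @param offsets optional named numeric vector of per-entry shifts (ppm).
#' @param label label for the result.
#' @return an `nmr_spectrum`.
#' @export
render_mixture <- function(library, axis, concentrations, offsets = NULL,
                           label = "mixture") {
  stopifnot(inherits(library, "nmr_library"))
  known <- c(names(library$entries), library$internal_standard$name)
  bad <- setdiff(names(concentrations), known)
  if (length(bad))
    stop(sprintf("unknown entry name(s) in concentrations: %s",
                 paste(bad, collapse = ", ")))
  vals <- numeric(n_bins(axis))
  for (nm in names(concentrations)) {
    if (concentrations[[nm]] == 0) next
    entry <- if (nm == library$internal_standard$name)
      library$internal_standard else library$entries[[nm]]
    off <- if (!is.null(offsets) && nm %in% names(offsets)) offsets[[nm]] else 0
    vals <- vals + render_entry(entry, axis, concentrations[[nm]],
                                shift_offset_ppm = off,
                                frequency_mhz = library$frequency_mhz)$intensities
  }
  nmr_spectrum(axis, vals, label = label)
}

#' Save a library to JSON / load it back
#'
#' The JSON schema is
#' `{frequency_mhz, internal_standard: {..., known_concentration_mM},
#' entries: [{name, role, reporter_center_ppm, window_halfwidth_ppm,
#' unit_response, components: [{center_ppm, rel_height, fwhm_hz}]}]}`.
#' On load, every `unit_response` is re-validated against the rendered
#' model (0.1% tolerance); duplicate names or a missing internal standard
#' are rejected.
#'
#' @param library an `nmr_library`.
#' @param path JSON file path.
#' @return `path` invisibly (save); an `nmr_library` (load).
#' @export
save_library <- function(library, path) {
  stopifnot(inherits(library, "nmr_library"))
  entry_json <- function(e) list(
    name = e$name, role = e$role,
    reporter_center_ppm = e$reporter_center_ppm,
    window_halfwidth_ppm = e$window_halfwidth_ppm,
    unit_response = e$unit_response,
    components = e$components)
  is_json <- entry_json(library$internal_standard)
  is_json$known_concentration_mM <- library$known_concentration_mM
  jsonlite::write_json(
    list(frequency_mhz = library$frequency_mhz,
         internal_standard = is_json,
         entries = lapply(library$entries, entry_json)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_library
#' @export
load_library <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  j <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  if (is.null(j$frequency_mhz)) stop(sprintf("%s: missing field frequency_mhz", path))
  if (is.null(j$internal_standard))
    stop(sprintf("%s: missing field internal_standard", path))
  freq <- j$frequency_mhz
  parse_entry <- function(e, where, role_override = NULL) {
    for (f in c("name", "reporter_center_ppm", "window_halfwidth_ppm",
                "unit_response", "components"))
      if (is.null(e[[f]]))
        stop(sprintf("%s: missing field %s.%s", path, where, f))
    role <- if (!is.null(role_override)) role_override else e$role
    metabolite_entry(e$name, as.data.frame(e$components),
                     reporter_center_ppm = e$reporter_center_ppm,
                     window_halfwidth_ppm = e$window_halfwidth_ppm,
                     role = role, unit_response = e$unit_response,
                     frequency_mhz = freq)
  }
  entries <- lapply(seq_along(j$entries), function(i)
    parse_entry(j$entries[[i]], sprintf("entries[%d]", i)))
  is_raw <- j$internal_standard
  if (is.null(is_raw$known_concentration_mM))
    stop(sprintf("%s: missing field internal_standard.known_concentration_mM", path))
  is_entry <- parse_entry(is_raw, "internal_standard", role_override = "target")
  nmr_library(entries, is_entry,
              known_concentration_mM = is_raw$known_concentration_mM,
              frequency_mhz = freq)
}
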