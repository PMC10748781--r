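#' Write a spectrum to delimited text with a JSON axis sidecar
#'
#' The main file holds two tab-separated columns (ppm, intensity) with
#' '#'-prefixed comment lines; values are printed with 17 significant digits
#' so that a write/read round trip reproduces intensities bit-exactly. Axis
#' metadata (segments, bin width, frequency, label) goes to `<path>.json`.
#'
#' @param spectrum an `nmr_spectrum`.
#' @param path output file path.
#' @param sidecar write the JSON sidecar (default TRUE).
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path, sidecar = TRUE) {
  stopifnot(inherits(spectrum, "nmr_spectrum"))
  cent <- bin_centers(spectrum$axis)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# label: %s", spectrum$label), con)
  writeLines(sprintf("%.17g\t%.17g", cent, spectrum$intensities), con)
  if (isTRUE(sidecar)) {
    meta <- list(
      segments = spectrum$axis$segments[, c("start_ppm", "end_ppm")],
      bin_width_ppm = spectrum$axis$segments$bin_width_ppm[1],
      frequency_mhz = spectrum$axis$frequency_mhz,
      label = spectrum$label)
    jsonlite::write_json(meta, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a spectrum from delimited text
#'
#' Accepts tab- or comma-delimited two-column text with '#' comments. Axis
#' metadata is taken from the `<path>.json` sidecar when present, from the
#' `axis` argument otherwise, or, failing both, inferred from the ppm column
#' (constant spacing; gaps larger than 1.5 bins split segments).
#'
#' @param path input file path.
#' @param axis optional `nmr_axis` to validate against.
#' @return an `nmr_spectrum`.
#' @export
read_spectrum <- function(path, axis = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  label <- ""
  lab_line <- grep("^# label:", lines, value = TRUE)
  if (length(lab_line)) label <- trimws(sub("^# label:", "", lab_line[1]))

  rows <- which(keep)
  if (!length(rows)) stop(sprintf("%s: no data rows", path))
  parts <- strsplit(trimws(lines[rows]), "[\t,]+|\\s+")
  nc <- lengths(parts)
  if (any(nc != 2L))
    stop(sprintf("%s: line %d: expected 2 columns, found %d",
                 path, rows[which(nc != 2L)[1]], nc[which(nc != 2L)[1]]))
  m <- matrix(suppressWarnings(as.numeric(unlist(parts))),
              ncol = 2L, byrow = TRUE)
  if (any(is.na(m))) {
    bad <- which(is.na(m[, 1]) | is.na(m[, 2]))[1]
    stop(sprintf("%s: line %d: non-numeric cell", path, rows[bad]))
  }
  ppm <- m[, 1]; y <- m[, 2]

  sidecar <- paste0(path, ".json")
  if (is.null(axis) && file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    axis <- build_axis(
      regions = lapply(seq_len(nrow(meta$segments)), function(i)
        c(meta$segments$start_ppm[i], meta$segments$end_ppm[i])),
      bin_width_ppm = meta$bin_width_ppm,
      frequency_mhz = meta$frequency_mhz)
    if (label == "" && !is.null(meta$label)) label <- meta$label
  }
  if (is.null(axis)) axis <- infer_axis(ppm)
  if (length(y) != n_bins(axis))
    stop(sprintf("%s: %d data rows but axis declares %d bins",
                 path, length(y), n_bins(axis)))
  nmr_spectrum(axis, y, label = label)
}

# Reconstruct an axis from a vector of bin centres (constant spacing within
# segments; a jump of more than 1.5 bin widths starts a new segment).
infer_axis <- function(ppm, frequency_mhz = 600) {
  if (length(ppm) < 2L) stop("cannot infer an axis from fewer than 2 bins")
  d <- diff(ppm)
  w <- stats::median(d)
  if (w <= 0) stop("ppm column must be ascending to infer an axis")
  breaks <- which(d > 1.5 * w)
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, length(ppm))
  regions <- Map(function(s, e) c(ppm[s] - w / 2, ppm[e] + w / 2), starts, ends)
  build_axis(regions, bin_width_ppm = w, frequency_mhz = frequency_mhz)
}

#' Write several spectra sharing one axis as a wide table
#'
#' First column ppm, one column per spectrum (column names = labels).
#'
#' @param spectra list of `nmr_spectrum` on a common axis.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum_table <- function(spectra, path) {
  stopifnot(length(spectra) >= 1L)
  ax <- spectra[[1]]$axis
  for (s in spectra)
    if (!axes_equal(s$axis, ax)) stop("all spectra must share one axis")
  labels <- vapply(seq_along(spectra), function(i) {
    l <- spectra[[i]]$label
    if (nzchar(l)) l else sprintf("spectrum_%d", i)
  }, character(1))
  m <- cbind(ppm = bin_centers(ax),
             do.call(cbind, lapply(spectra, `[[`, "intensities")))
  colnames(m) <- c("ppm", labels)
  utils::write.table(format(m, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a wide multi-spectrum table
#'
#' @param path input path (first column ppm, one column per spectrum).
#' @param axis optional `nmr_axis`; inferred from the ppm column otherwise.
#' @return named list of `nmr_spectrum`.
#' @export
read_spectrum_table <- function(path, axis = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, comment.char = "#")
  if (ncol(df) < 2L) stop(sprintf("%s: expected ppm plus >= 1 spectrum column", path))
  if (is.null(axis)) axis <- infer_axis(as.numeric(df[[1]]))
  out <- lapply(names(df)[-1], function(nm)
    nmr_spectrum(axis, as.numeric(df[[nm]]), label = nm))
  names(out) <- names(df)[-1]
  out
}
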