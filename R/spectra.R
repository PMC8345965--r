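## Emission-spectrum containers and tabular I/O.
##
## Spectra are stored un-rescaled: the downstream denaturation statistic is a
## ratio of intensities and therefore invariant to per-spectrum scaling, so
## any display normalization is presentation-only.

#' Construct a single fluorescence emission spectrum
#'
#' One emission scan of a sample at one incubation time. Wavelengths must be a
#' strictly increasing grid with one finite, non-negative intensity per point.
#' For the denaturation statistic to be computable the grid must cover at
#' least 330--365 nm (the scans of interest span 300--400 nm).
#'
#' @param sample_id Character label for the sample.
#' @param time_h Incubation time in hours (>= 0).
#' @param wavelengths Numeric, strictly increasing emission wavelengths (nm).
#' @param intensities Numeric fluorescence intensities (arbitrary units),
#'   same length as `wavelengths`, finite and >= 0.
#' @param condition `"urea"` (denaturing, 8 M urea) or `"control"` (no urea).
#' @param excitation_nm Excitation wavelength in nm (default 280).
#' @return An object of class `emission_spectrum`.
#' @export
emission_spectrum <- function(sample_id, time_h, wavelengths, intensities,
                              condition = c("urea", "control"),
                              excitation_nm = 280) {
  condition <- match.arg(condition)
  sample_id <- as.character(sample_id)
  time_h <- as.numeric(time_h)
  wavelengths <- as.numeric(wavelengths)
  intensities <- as.numeric(intensities)
  if (length(sample_id) != 1L || is.na(sample_id) || !nzchar(sample_id))
    stop_format("sample_id must be a single non-empty string")
  if (length(time_h) != 1L || !is.finite(time_h) || time_h < 0)
    stop_format("time_h must be a single finite number >= 0 (sample '%s')",
                sample_id)
  if (length(wavelengths) != length(intensities))
    stop_format("wavelengths and intensities differ in length (sample '%s', t = %g h)",
                sample_id, time_h)
  if (!length(wavelengths))
    stop_format("a spectrum needs at least 1 grid point (sample '%s', t = %g h)",
                sample_id, time_h)
  if (length(wavelengths) > 1L && !is_strictly_increasing(wavelengths))
    stop_format("wavelength grid must be strictly increasing (sample '%s', t = %g h)",
                sample_id, time_h)
  if (any(!is.finite(intensities)) || any(intensities < 0))
    stop_format("intensities must be finite and >= 0 (sample '%s', t = %g h)",
                sample_id, time_h)
  structure(
    list(sample_id = sample_id, time_h = time_h,
         excitation_nm = as.numeric(excitation_nm),
         wavelengths = wavelengths, intensities = intensities,
         condition = condition),
    class = "emission_spectrum")
}

#' @export
print.emission_spectrum <- function(x, ...) {
  cat(sprintf("<emission_spectrum> %s  t = %g h  %s  %d points (%.1f-%.1f nm)\n",
              x$sample_id, x$time_h, x$condition, length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' Does a spectrum's grid cover the wavelengths needed for rfi?
#'
#' The rfi statistic reads intensities at 330, 344 and 365 nm, so the grid
#' must cover at least \[330, 365\] nm.
#'
#' @param spectrum An `emission_spectrum`.
#' @return Logical scalar.
#' @export
covers_rfi_band <- function(spectrum) {
  min(spectrum$wavelengths) <= 330 && max(spectrum$wavelengths) >= 365
}

#' Construct a time series of emission spectra for one sample
#'
#' @param spectra List of [emission_spectrum()] objects for a single sample,
#'   sharing one condition and one excitation wavelength. They are ordered by
#'   incubation time; duplicate times are an error (silent averaging would
#'   hide acquisition mistakes).
#' @return An object of class `spectral_series`.
#' @export
spectral_series <- function(spectra) {
  if (!length(spectra)) stop_format("a spectral series needs at least one spectrum")
  ok <- vapply(spectra, inherits, logical(1), "emission_spectrum")
  if (!all(ok)) stop_format("all elements must be emission_spectrum objects")
  ids <- unique(vapply(spectra, `[[`, character(1), "sample_id"))
  if (length(ids) != 1L)
    stop_format("a spectral series must hold a single sample, got: %s",
                paste(ids, collapse = ", "))
  conds <- unique(vapply(spectra, `[[`, character(1), "condition"))
  if (length(conds) != 1L)
    stop_format("sample '%s': spectra mix conditions (%s)", ids,
                paste(conds, collapse = ", "))
  exc <- unique(vapply(spectra, `[[`, numeric(1), "excitation_nm"))
  if (length(exc) != 1L)
    stop_format("sample '%s': spectra mix excitation wavelengths", ids)
  times <- vapply(spectra, `[[`, numeric(1), "time_h")
  if (anyDuplicated(round(times / 1e-6)))
    stop_format("sample '%s': duplicate incubation time(s) %s", ids,
                paste(unique(times[duplicated(times)]), collapse = ", "))
  spectra <- spectra[order(times)]
  structure(
    list(sample_id = ids, condition = conds, excitation_nm = exc,
         spectra = spectra),
    class = "spectral_series")
}

#' @export
print.spectral_series <- function(x, ...) {
  times <- vapply(x$spectra, `[[`, numeric(1), "time_h")
  cat(sprintf("<spectral_series> %s  %s  %d times: %s h\n", x$sample_id,
              x$condition, length(times), paste(times, collapse = ", ")))
  invisible(x)
}

series_times <- function(series) {
  vapply(series$spectra, `[[`, numeric(1), "time_h")
}

#' Read emission spectra from a tabular text file
#'
#' The canonical on-disk format is long CSV with columns `sample_id`,
#' `condition`, `time_h`, `wavelength_nm`, `intensity` (UTF-8, `.` decimal
#' separator). A `wide` dialect is supported read-only for instrument exports:
#' one `wavelength_nm` column plus one column per time point named `t<time>h`
#' (e.g. `t0h`, `t8h`, `t26h`); sample id and condition then default to the
#' file name stem and `"urea"` unless given.
#'
#' @param path Path to an existing file.
#' @param dialect `"long"` (default) or `"wide"`.
#' @param sample_id,condition Used only by the wide dialect.
#' @return A list of [spectral_series()], one per sample, in first-appearance
#'   order. Row order in the file is irrelevant.
#' @export
read_spectra_table <- function(path, dialect = c("long", "wide"),
                               sample_id = NULL, condition = "urea") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_format("file not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (dialect == "long") {
    needed <- c("sample_id", "condition", "time_h", "wavelength_nm", "intensity")
    missing <- setdiff(needed, names(df))
    if (length(missing))
      stop_format("missing required column(s): %s", paste(missing, collapse = ", "))
    split_by_sample <- split(df, factor(df$sample_id, levels = unique(df$sample_id)))
    lapply(split_by_sample, function(d) {
      specs <- lapply(split(d, d$time_h), function(s) {
        o <- order(s$wavelength_nm)
        emission_spectrum(s$sample_id[1], s$time_h[1],
                          s$wavelength_nm[o], s$intensity[o],
                          condition = s$condition[1])
      })
      spectral_series(specs)
    })
  } else {
    if (!"wavelength_nm" %in% names(df))
      stop_format("missing required column(s): wavelength_nm")
    tcols <- grep("^t[0-9.]+h$", names(df), value = TRUE)
    if (!length(tcols))
      stop_format("wide dialect needs time columns named like 't8h'")
    if (is.null(sample_id))
      sample_id <- sub("\\.[^.]*$", "", basename(path))
    o <- order(df$wavelength_nm)
    specs <- lapply(tcols, function(cn) {
      t <- as.numeric(sub("^t([0-9.]+)h$", "\\1", cn))
      emission_spectrum(sample_id, t, df$wavelength_nm[o], df[[cn]][o],
                        condition = condition)
    })
    stats::setNames(list(spectral_series(specs)), sample_id)
  }
}

#' Write spectral series to long CSV
#'
#' Inverse of [read_spectra_table()] for the long dialect:
#' `read_spectra_table(write_spectra_table(x))` reproduces `x` up to
#' floating-point round-trip.
#'
#' @param series A [spectral_series()] or a list of them (non-empty).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectra_table <- function(series, path) {
  if (inherits(series, "spectral_series")) series <- list(series)
  if (!length(series)) stop_format("no series to write")
  rows <- lapply(series, function(s) {
    do.call(rbind, lapply(s$spectra, function(sp) {
      data.frame(sample_id = sp$sample_id, condition = sp$condition,
                 time_h = sp$time_h, wavelength_nm = sp$wavelengths,
                 intensity = sp$intensities)
    }))
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Resample a spectrum onto a new wavelength grid
#'
#' Linear interpolation onto `grid`; values at original grid points are
#' unchanged. The grid must lie within the spectrum's span (no extrapolation).
#'
#' @param spectrum An `emission_spectrum`.
#' @param grid Strictly increasing wavelengths (nm) within the span.
#' @return A new `emission_spectrum` on `grid`.
#' @export
resample_to_grid <- function(spectrum, grid) {
  grid <- as.numeric(grid)
  if (!is_strictly_increasing(grid))
    stop_format("target grid must be strictly increasing")
  lo <- min(spectrum$wavelengths); hi <- max(spectrum$wavelengths)
  if (min(grid) < lo - 1e-6 || max(grid) > hi + 1e-6)
    stop_format("target grid [%g, %g] extends beyond the spectrum span [%g, %g]",
                min(grid), max(grid), lo, hi)
  # exact hits (within 1e-6 nm) return stored values; others interpolate
  yi <- stats::approx(spectrum$wavelengths, spectrum$intensities, xout = grid,
                      ties = "ordered")$y
  idx <- match(round(grid / 1e-6), round(spectrum$wavelengths / 1e-6))
  hit <- !is.na(idx)
  yi[hit] <- spectrum$intensities[idx[hit]]
  emission_spectrum(spectrum$sample_id, spectrum$time_h, grid, yi,
                    condition = spectrum$condition,
                    excitation_nm = spectrum$excitation_nm)
}
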