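## The denaturation statistic and its normalization.
##
## As HDL apolipoproteins unfold in urea, tryptophan emission redshifts:
## intensity at 330 nm (buried Trp) falls while 344 and 365 nm (solvent-
## exposed Trp) rise. The ratio of fluorescence intensities
##   rfi = (Em344 + Em365) / Em330
## increases monotonically with denaturation, and is invariant to any
## per-spectrum rescaling. The time course is anchored so that the 0 h value
## maps to 0% denaturation and the 26 h value to 100%.

RFI_NUM_NM <- c(344, 365)
RFI_DEN_NM <- 330

#' Read an intensity off a spectrum at an arbitrary wavelength
#'
#' Exact grid hits (within 1e-6 nm) return the stored value; otherwise the
#' intensity is linearly interpolated between the bracketing grid points.
#'
#' @param spectrum An [emission_spectrum()].
#' @param wavelength Query wavelength in nm, inside the spectrum's span.
#' @return Intensity in arbitrary units.
#' @export
intensity_at <- function(spectrum, wavelength) {
  stopifnot(inherits(spectrum, "emission_spectrum"),
            length(wavelength) == 1L, is.finite(wavelength))
  w <- spectrum$wavelengths
  if (wavelength < min(w) - 1e-9 || wavelength > max(w) + 1e-9)
    stop_format("wavelength %g nm outside the spectrum span [%g, %g] (sample '%s', t = %g h)",
                wavelength, min(w), max(w), spectrum$sample_id, spectrum$time_h)
  idx <- match(round(wavelength / 1e-6), round(w / 1e-6))
  if (!is.na(idx)) return(spectrum$intensities[idx])
  stats::approx(w, spectrum$intensities, xout = wavelength,
                ties = "ordered")$y
}

#' Compute the ratio of fluorescence intensities (rfi)
#'
#' `rfi = (Em344 + Em365) / Em330`, the assay's denaturation statistic.
#' Intensities are read at the exact wavelengths 330, 344 and 365 nm
#' (interpolated if off-grid), not at local maxima near them.
#'
#' @param spectrum An [emission_spectrum()] whose grid covers 330--365 nm.
#' @return Unitless rfi value (> 0 for non-degenerate spectra).
#' @export
compute_rfi <- function(spectrum) {
  if (!covers_rfi_band(spectrum))
    stop_format("spectrum does not cover 330-365 nm (sample '%s', t = %g h)",
                spectrum$sample_id, spectrum$time_h)
  em330 <- intensity_at(spectrum, RFI_DEN_NM)
  if (em330 <= 0)
    stop_format("degenerate spectrum: Em330 = %g <= 0 (sample '%s', t = %g h)",
                em330, spectrum$sample_id, spectrum$time_h)
  (intensity_at(spectrum, RFI_NUM_NM[1]) + intensity_at(spectrum, RFI_NUM_NM[2])) / em330
}

#' Build a denaturation time course of rfi values
#'
#' Computes one rfi per spectrum and records the anchor times used for the
#' percent-denaturation normalization. Both anchor times must be present in
#' the series (within 1e-6 h); the assay's convention is 0 h and 26 h.
#'
#' @param series A [spectral_series()].
#' @param anchor_t0 Basal anchor time in hours (default 0; maps to 0%).
#' @param anchor_tmax Terminal anchor time in hours (default 26; maps to 100%).
#' @return An object of class `denaturation_series` with fields `sample_id`,
#'   `condition`, `times`, `rfi_values`, `anchor_t0`, `anchor_tmax`.
#' @export
rfi_series <- function(series, anchor_t0 = 0, anchor_tmax = 26) {
  stopifnot(inherits(series, "spectral_series"))
  times <- series_times(series)
  for (anchor in c(anchor_t0, anchor_tmax)) {
    if (!any(abs(times - anchor) < 1e-6))
      stop_format("sample '%s': no spectrum at anchor time %g h",
                  series$sample_id, anchor)
  }
  rfi <- vapply(series$spectra, compute_rfi, numeric(1))
  structure(
    list(sample_id = series$sample_id, condition = series$condition,
         times = times, rfi_values = rfi,
         anchor_t0 = anchor_t0, anchor_tmax = anchor_tmax),
    class = "denaturation_series")
}

#' @export
print.denaturation_series <- function(x, ...) {
  cat(sprintf("<denaturation_series> %s  %s  %d times, rfi %.3f..%.3f (anchors %g/%g h)\n",
              x$sample_id, x$condition, length(x$times),
              min(x$rfi_values), max(x$rfi_values), x$anchor_t0, x$anchor_tmax))
  invisible(x)
}

#' Normalize an rfi time course to percent denaturation
#'
#' Affine map anchored at the basal and terminal scans:
#' `pct(t) = 100 * (rfi(t) - rfi0) / (rfi_max - rfi0)`, so that the value at
#' the basal anchor is exactly 0 and at the terminal anchor exactly 100.
#' Values are not clamped to \[0, 100\]: points outside that range (noisy
#' anchors) are reported and flagged in the `out_of_range` attribute rather
#' than masked. Series whose terminal rfi is below the basal rfi (inverted
#' anchors) are rejected.
#'
#' @param series A `denaturation_series` from [rfi_series()].
#' @return An object of class `normalized_series` with fields `sample_id`,
#'   `times`, `percent_denaturation`, `anchor_t0`, `anchor_tmax` and a logical
#'   `out_of_range` quality flag per point.
#' @export
normalize_to_percent <- function(series) {
  stopifnot(inherits(series, "denaturation_series"))
  i0 <- which(abs(series$times - series$anchor_t0) < 1e-6)[1]
  imax <- which(abs(series$times - series$anchor_tmax) < 1e-6)[1]
  rfi0 <- series$rfi_values[i0]
  rfimax <- series$rfi_values[imax]
  if (rfimax == rfi0)
    stop_format("sample '%s': degenerate anchors, rfi(%g h) == rfi(%g h) == %g",
                series$sample_id, series$anchor_t0, series$anchor_tmax, rfi0)
  if (rfimax < rfi0)
    stop_format("sample '%s': inverted anchors, rfi(%g h) = %g < rfi(%g h) = %g",
                series$sample_id, series$anchor_tmax, rfimax,
                series$anchor_t0, rfi0)
  # ratio first, then scale: keeps the anchors bit-exact at 0 and 100
  pct <- 100 * ((series$rfi_values - rfi0) / (rfimax - rfi0))
  structure(
    list(sample_id = series$sample_id, times = series$times,
         percent_denaturation = pct,
         anchor_t0 = series$anchor_t0, anchor_tmax = series$anchor_tmax,
         out_of_range = pct < 0 | pct > 100),
    class = "normalized_series")
}

#' Construct a normalized percent-denaturation series directly
#'
#' Mostly useful for feeding externally normalized data (or exact logistic
#' test curves) to the kinetics fitter; [normalize_to_percent()] is the
#' assay's route.
#'
#' @param sample_id Sample label.
#' @param times Strictly increasing times in hours.
#' @param percent_denaturation Percent values, one per time.
#' @param anchor_t0,anchor_tmax Anchor times in hours.
#' @return A `normalized_series`.
#' @export
normalized_series <- function(sample_id, times, percent_denaturation,
                              anchor_t0 = 0, anchor_tmax = 26) {
  times <- as.numeric(times)
  percent_denaturation <- as.numeric(percent_denaturation)
  if (length(times) != length(percent_denaturation))
    stop_format("times and percent_denaturation differ in length")
  if (!is_strictly_increasing(times))
    stop_format("times must be strictly increasing and unique")
  structure(
    list(sample_id = as.character(sample_id), times = times,
         percent_denaturation = percent_denaturation,
         anchor_t0 = anchor_t0, anchor_tmax = anchor_tmax,
         out_of_range = percent_denaturation < 0 | percent_denaturation > 100),
    class = "normalized_series")
}

#' @export
print.normalized_series <- function(x, ...) {
  cat(sprintf("<normalized_series> %s  %d times, %.1f..%.1f%%\n",
              x$sample_id, length(x$times),
              min(x$percent_denaturation), max(x$percent_denaturation)))
  invisible(x)
}

#' Percent denaturation at a fixed scoring time
#'
#' The stability score is the percent denaturation at a fixed incubation
#' time, 8 h by default (near the healthy-donor DT50, where sensitivity to
#' departures from 50% is maximal). With `policy = "exact"` the series must
#' contain a measurement at `t_query`; `policy = "interpolate"` linearly
#' interpolates between the neighboring times.
#'
#' @param norm A `normalized_series`.
#' @param t_query Scoring time in hours (default 8), within the observed span.
#' @param policy `"exact"` (default) or `"interpolate"`.
#' @return Percent denaturation at `t_query`.
#' @export
percent_at_time <- function(norm, t_query = 8,
                            policy = c("exact", "interpolate")) {
  stopifnot(inherits(norm, "normalized_series"))
  policy <- match.arg(policy)
  if (t_query < min(norm$times) - 1e-9 || t_query > max(norm$times) + 1e-9)
    stop_format("sample '%s': query time %g h outside observed span [%g, %g] h",
                norm$sample_id, t_query, min(norm$times), max(norm$times))
  idx <- which(abs(norm$times - t_query) < 1e-6)
  if (policy == "exact") {
    if (!length(idx))
      stop_format("sample '%s': no measurement at %g h (policy = exact); use policy = 'interpolate'",
                  norm$sample_id, t_query)
    return(norm$percent_denaturation[idx[1]])
  }
  if (length(idx)) return(norm$percent_denaturation[idx[1]])
  stats::approx(norm$times, norm$percent_denaturation, xout = t_query,
                ties = "ordered")$y
}

#' Score a set of spectral series at a fixed time
#'
#' Convenience wrapper running [rfi_series()], [normalize_to_percent()] and
#' [percent_at_time()] over a list of series; the CLI's `score` subcommand.
#'
#' @param series_list List of [spectral_series()].
#' @param time_h Scoring time (default 8 h).
#' @param policy Passed to [percent_at_time()].
#' @param anchor_t0,anchor_tmax Passed to [rfi_series()].
#' @return A data.frame with columns `sample_id`, `condition`, `rfi_0h`,
#'   `rfi_26h`, `pct_denat_at_time`, `quality_flags`.
#' @export
score_samples <- function(series_list, time_h = 8, policy = "exact",
                          anchor_t0 = 0, anchor_tmax = 26) {
  if (inherits(series_list, "spectral_series")) series_list <- list(series_list)
  rows <- lapply(series_list, function(s) {
    d <- rfi_series(s, anchor_t0 = anchor_t0, anchor_tmax = anchor_tmax)
    n <- normalize_to_percent(d)
    flags <- if (any(n$out_of_range)) "out_of_range" else ""
    data.frame(
      sample_id = d$sample_id, condition = d$condition,
      rfi_0h = d$rfi_values[which(abs(d$times - anchor_t0) < 1e-6)[1]],
      rfi_26h = d$rfi_values[which(abs(d$times - anchor_tmax) < 1e-6)[1]],
      pct_denat_at_time = percent_at_time(n, time_h, policy = policy),
      quality_flags = flags)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
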