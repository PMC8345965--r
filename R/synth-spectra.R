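## Synthetic spectra, denaturation kinetics, and densitograms.
##
## The spectral generator emulates what the assay observes: tryptophan
## emission as a mixture of a buried band at 330 nm and two solvent-exposed
## bands at 344 and 365 nm whose combined weight grows with the unfolded
## fraction f. A fraction kappa of the buried fluorescence is transferred to
## the exposed bands at full denaturation (the 330 nm band decreases but
## never vanishes, matching the assay's observations); a uniform exponential
## bleach models the gradual overall intensity decay, and cancels out of the
## rfi ratio.

#' Parameters of the synthetic three-band emission model
#'
#' @param band_centers Band centers in nm, strictly increasing
#'   (default c(330, 344, 365): buried, exposed, exposed).
#' @param sigma_buried,sigma_exposed Gaussian band widths in nm (defaults 16
#'   and 20).
#' @param exposed_weights Unitless split of transferred fluorescence between
#'   the 344 and 365 nm bands (default c(0.6, 0.4); normalized to sum 1).
#' @param base_amplitude Overall intensity scale in arbitrary units
#'   (default 1000).
#' @param kappa Maximal fraction of fluorescence transferred from the buried
#'   to the exposed bands at full denaturation, in (0, 1] (default 0.8: the
#'   buried band persists at the end of the time course).
#' @param bleach_rate Exponential intensity decay per hour, >= 0
#'   (default 0.01).
#' @param noise_sd Additive Gaussian noise sd in AU, >= 0 (default 0).
#' @return An object of class `spectral_model_params`.
#' @export
spectral_model_params <- function(band_centers = c(330, 344, 365),
                                  sigma_buried = 16, sigma_exposed = 20,
                                  exposed_weights = c(0.6, 0.4),
                                  base_amplitude = 1000,
                                  kappa = 0.8, bleach_rate = 0.01,
                                  noise_sd = 0) {
  if (length(band_centers) != 3L || !is_strictly_increasing(band_centers))
    stop_format("band_centers must be 3 strictly increasing wavelengths")
  if (sigma_buried <= 0 || sigma_exposed <= 0)
    stop_format("band sigmas must be > 0")
  if (length(exposed_weights) != 2L || any(exposed_weights < 0) ||
      sum(exposed_weights) <= 0)
    stop_format("exposed_weights must be 2 non-negative weights")
  if (!(kappa > 0 && kappa <= 1)) stop_format("kappa must be in (0, 1]")
  if (bleach_rate < 0) stop_format("bleach_rate must be >= 0")
  if (noise_sd < 0) stop_format("noise_sd must be >= 0")
  structure(
    list(band_centers = band_centers, sigma_buried = sigma_buried,
         sigma_exposed = sigma_exposed,
         exposed_weights = exposed_weights / sum(exposed_weights),
         base_amplitude = base_amplitude, kappa = kappa,
         bleach_rate = bleach_rate, noise_sd = noise_sd),
    class = "spectral_model_params")
}

#' True logistic unfolding kinetics for simulation
#'
#' Unfolded fraction `f(t) = 1 / (1 + exp(-(t - t50) / slope_b))`.
#'
#' @param t50 Inflection time in hours (> 0; default 8, the healthy-donor
#'   DT50).
#' @param slope_b Characteristic width in hours (> 0; default 1.5).
#' @param sample_times Scan times in hours (default hourly 0--12 plus the
#'   26 h terminal scan, the assay's acquisition schedule).
#' @return An object of class `kinetics_true_params`.
#' @export
kinetics_true_params <- function(t50 = 8, slope_b = 1.5,
                                 sample_times = c(0:12, 26)) {
  sample_times <- sort(unique(as.numeric(sample_times)))
  if (!length(sample_times)) stop_format("sample_times must be non-empty")
  if (t50 <= 0 || slope_b <= 0) stop_format("t50 and slope_b must be > 0")
  if (t50 < min(sample_times) || t50 > max(sample_times))
    stop_format("t50 = %g h lies outside the sampled span [%g, %g] h",
                t50, min(sample_times), max(sample_times))
  structure(list(t50 = t50, slope_b = slope_b, sample_times = sample_times),
            class = "kinetics_true_params")
}

#' Logistic unfolded fraction
#'
#' @param kparams A [kinetics_true_params()].
#' @param t Times in hours.
#' @return Unfolded fraction in (0, 1).
#' @export
unfolded_fraction <- function(kparams, t) {
  1 / (1 + exp(-(t - kparams$t50) / kparams$slope_b))
}

# Unit-height Gaussian band
gauss_band <- function(lambda, center, sigma) exp(-(lambda - center)^2 / (2 * sigma^2))

# Noise-free model intensity at unfolded fraction f (relative to amplitude 1,
# no bleach). Shared by the generator and tests.
model_intensity <- function(params, lambda, f) {
  bc <- params$band_centers
  w <- params$exposed_weights
  (1 - params$kappa * f) * gauss_band(lambda, bc[1], params$sigma_buried) +
    params$kappa * f * (w[1] * gauss_band(lambda, bc[2], params$sigma_exposed) +
                        w[2] * gauss_band(lambda, bc[3], params$sigma_exposed))
}

#' Simulate one emission spectrum at a given unfolded fraction
#'
#' `I(lambda) = A exp(-bleach_rate t) [(1 - kappa f) G(lambda; 330, s_b) +
#' kappa f (w344 G(lambda; 344, s_e) + w365 G(lambda; 365, s_e))] + noise`,
#' truncated at 0, where G is a unit-height Gaussian band.
#'
#' @param params A [spectral_model_params()].
#' @param unfolded_fraction Unfolded fraction f in \[0, 1\].
#' @param time_h Incubation time in hours (drives bleach).
#' @param rng_seed Integer seed (noise reproducibility); `NULL` uses the
#'   current RNG state.
#' @param wavelengths Emission grid in nm (default 300--400 step 1).
#' @param sample_id,condition Labels for the returned spectrum.
#' @return An [emission_spectrum()].
#' @export
simulate_spectrum <- function(params, unfolded_fraction, time_h,
                              rng_seed = NULL,
                              wavelengths = seq(300, 400, by = 1),
                              sample_id = "synthetic", condition = "urea") {
  stopifnot(inherits(params, "spectral_model_params"))
  f <- unfolded_fraction
  if (!is.finite(f) || f < 0 || f > 1)
    stop_format("unfolded_fraction must be in [0, 1], got %g", f)
  shape <- model_intensity(params, wavelengths, f)
  amp <- params$base_amplitude * exp(-params$bleach_rate * time_h)
  intens <- amp * shape
  if (params$noise_sd > 0) {
    intens <- with_seed(rng_seed,
                        intens + stats::rnorm(length(intens), 0, params$noise_sd))
  }
  emission_spectrum(sample_id, time_h, wavelengths, pmax(intens, 0),
                    condition = condition)
}

#' Simulate a full denaturation time series of spectra
#'
#' One spectrum per sample time, with the unfolded fraction following the
#' logistic kinetics. With `noise_sd = 0` and `bleach_rate = 0` the
#' downstream rfi is strictly increasing in time for any kappa in (0, 1\]
#' (bleach cancels out of the ratio in any case). For `condition = "control"`
#' (no urea) the unfolded fraction is held at 0, producing the flat rfi trace
#' of an undenatured sample.
#'
#' @param kparams A [kinetics_true_params()].
#' @param sparams A [spectral_model_params()].
#' @param rng_seed Integer seed for the noise; `NULL` uses current RNG state.
#' @param sample_id Label.
#' @param condition `"urea"` (default) or `"control"`.
#' @param wavelengths Emission grid in nm.
#' @return A [spectral_series()].
#' @export
simulate_denaturation_series <- function(kparams, sparams, rng_seed = NULL,
                                         sample_id = "synthetic",
                                         condition = "urea",
                                         wavelengths = seq(300, 400, by = 1)) {
  stopifnot(inherits(kparams, "kinetics_true_params"),
            inherits(sparams, "spectral_model_params"))
  with_seed(rng_seed, {
    specs <- lapply(kparams$sample_times, function(t) {
      f <- if (condition == "control") 0 else unfolded_fraction(kparams, t)
      simulate_spectrum(sparams, f, t, rng_seed = NULL,
                        wavelengths = wavelengths, sample_id = sample_id,
                        condition = condition)
    })
    spectral_series(specs)
  })
}

#' Simulate a native-PAGE densitogram with a prescribed free-protein fraction
#'
#' The trace is a sum of Gaussian peaks on a migration axis: `n_hdl_peaks`
#' lipoprotein-associated peaks in the low-migration region and (when
#' `free_fraction_pct > 0`) one well-separated free-protein peak at high
#' migration. Peak weights are set so that the free-protein share of the
#' total area equals `free_fraction_pct`; peaks are fully contained in the
#' span, so trapezoidal integration recovers the construction to better than
#' 0.1 percentage points.
#'
#' @param free_fraction_pct Free-protein share of total protein area, percent
#'   in \[0, 100\].
#' @param n_hdl_peaks Number of HDL-associated peaks (>= 1; HDL subclasses).
#' @param rng_seed Integer seed jittering peak positions and widths.
#' @param sample_id,time_h Labels for the returned trace.
#' @return A [densitogram()] (protein stain) carrying its generating regions
#'   in `attr(, "regions")` and the construction value in
#'   `attr(, "true_free_fraction_pct")`.
#' @export
simulate_densitogram <- function(free_fraction_pct, n_hdl_peaks = 3,
                                 rng_seed = NULL, sample_id = "synthetic",
                                 time_h = 0) {
  if (!is.finite(free_fraction_pct) || free_fraction_pct < 0 ||
      free_fraction_pct > 100)
    stop_format("free_fraction_pct must be in [0, 100], got %g", free_fraction_pct)
  if (n_hdl_peaks < 1) stop_format("n_hdl_peaks must be >= 1")
  with_seed(rng_seed, {
    pos <- seq(0, 100, by = 0.05)
    # HDL-associated peaks between 25 and 55; free protein peak near 80
    centers <- seq(28, 52, length.out = n_hdl_peaks) +
      stats::runif(n_hdl_peaks, -1, 1)
    widths <- stats::runif(n_hdl_peaks, 1.8, 2.6)
    hdl_w <- stats::runif(n_hdl_peaks, 0.5, 1)
    hdl_w <- hdl_w / sum(hdl_w) * (1 - free_fraction_pct / 100)
    free_center <- 80 + stats::runif(1, -1, 1)
    free_width <- stats::runif(1, 1.8, 2.6)
    trace <- rep(0, length(pos))
    for (i in seq_len(n_hdl_peaks)) {
      trace <- trace + hdl_w[i] / (widths[i] * sqrt(2 * pi)) *
        exp(-(pos - centers[i])^2 / (2 * widths[i]^2))
    }
    if (free_fraction_pct > 0) {
      trace <- trace + (free_fraction_pct / 100) / (free_width * sqrt(2 * pi)) *
        exp(-(pos - free_center)^2 / (2 * free_width^2))
    }
    d <- densitogram(sample_id, time_h, pos, trace, stain = "protein")
    regions <- list(peak_region("hdl_associated", 10, 67))
    if (free_fraction_pct > 0)
      regions <- c(regions, list(peak_region("free_protein", 67, 95)))
    attr(d, "regions") <- regions
    attr(d, "true_free_fraction_pct") <- free_fraction_pct
    d
  })
}
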