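# Shared fixtures and independent oracles for the test suite.

# A random but valid emission spectrum on the standard 300-400 nm grid.
random_spectrum <- function(seed, sample_id = paste0("r", seed)) {
  set.seed(seed)
  w <- seq(300, 400, by = 1)
  base <- 200 + 800 * exp(-(w - runif(1, 325, 350))^2 / (2 * runif(1, 10, 25)^2))
  emission_spectrum(sample_id, time_h = runif(1, 0, 26), wavelengths = w,
                    intensities = pmax(base + rnorm(length(w), 0, 20), 0))
}

# Three-number arithmetic oracle for rfi on a 1-nm grid spectrum.
rfi_oracle <- function(spectrum) {
  w <- spectrum$wavelengths
  (spectrum$intensities[w == 344] + spectrum$intensities[w == 365]) /
    spectrum$intensities[w == 330]
}

# Rescale a spectrum's intensities by c > 0.
scale_spectrum <- function(spectrum, c) {
  emission_spectrum(spectrum$sample_id, spectrum$time_h, spectrum$wavelengths,
                    c * spectrum$intensities, condition = spectrum$condition,
                    excitation_nm = spectrum$excitation_nm)
}

# Brute-force maximum bipartite matching (augmenting paths): the oracle for
# the greedy HDL-cholesterol matcher. adj[i, j] = TRUE if case i and control
# j are within tolerance.
max_matching_count <- function(adj) {
  n_left <- nrow(adj); n_right <- ncol(adj)
  match_r <- rep(0L, n_right)
  try_aug <- function(u, seen) {
    for (v in which(adj[u, ])) if (!seen[v]) {
      seen[v] <- TRUE
      if (match_r[v] == 0L || Recall(match_r[v], seen)) {
        match_r[v] <<- u
        return(TRUE)
      }
    }
    FALSE
  }
  count <- 0L
  for (u in seq_len(n_left)) {
    if (try_aug(u, rep(FALSE, n_right))) count <- count + 1L
  }
  count
}

# Minimal cohort-like table with given HDL-cholesterol values.
hdlc_table <- function(case_hdlc, control_hdlc) {
  data.frame(
    subject_id = sprintf("s%03d", seq_len(length(case_hdlc) + length(control_hdlc))),
    group = factor(rep(c("ACS", "control"),
                       c(length(case_hdlc), length(control_hdlc))),
                   levels = c("control", "ACS")),
    hdl_cholesterol = c(case_hdlc, control_hdlc))
}

# Noiseless synthetic pipeline: spectra -> rfi -> normalized series.
noiseless_normalized <- function(kparams = kinetics_true_params(),
                                 sparams = spectral_model_params()) {
  normalize_to_percent(rfi_series(simulate_denaturation_series(kparams, sparams)))
}
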