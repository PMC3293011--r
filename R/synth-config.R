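#' Default single-beat wave morphology for the eight synthesized leads
#'
#' Each lead is modeled as a sum of five Gaussian components (P, Q, R, S, T);
#' leads III, aVR, aVL and aVF are derived from I and II and therefore carry
#' no template of their own. Amplitudes are in mV, centers and widths in
#' seconds from beat onset. Timing is shared across leads so that QRS onset,
#' the J point and T end fall at the same phase in every lead, as on a real
#' simultaneous 12-lead recording.
#'
#' @return named list (one entry per basis lead) of 5x3 parameter matrices
#'   with rows P, Q, R, S, T and columns amp, center, width.
#' @export
default_wave_params <- function() {
  base_timing <- cbind(
    center = c(P = 0.200, Q = 0.355, R = 0.375, S = 0.395, T = 0.600),
    width  = c(P = 0.025, Q = 0.009, R = 0.012, S = 0.009, T = 0.055)
  )
  amps <- list(
    I  = c(P = 0.08, Q = -0.05, R = 0.70, S = -0.15, T = 0.25),
    II = c(P = 0.12, Q = -0.08, R = 1.00, S = -0.20, T = 0.35),
    V1 = c(P = 0.05, Q =  0.00, R = 0.20, S = -0.80, T = -0.10),
    V2 = c(P = 0.05, Q =  0.00, R = 0.40, S = -0.90, T = 0.25),
    V3 = c(P = 0.05, Q = -0.02, R = 0.60, S = -0.60, T = 0.30),
    V4 = c(P = 0.06, Q = -0.04, R = 1.10, S = -0.40, T = 0.35),
    V5 = c(P = 0.07, Q = -0.06, R = 1.20, S = -0.25, T = 0.30),
    V6 = c(P = 0.07, Q = -0.06, R = 0.90, S = -0.15, T = 0.25)
  )
  lapply(amps, function(a) cbind(amp = a, base_timing))
}

#' Configuration for the synthetic ECG cohort generator
#'
#' Bundles every knob of the generator: cohort composition (size, STEMI
#' prevalence, conditional probabilities of needing acute PCI), waveform
#' morphology, injected ST-elevation magnitudes, and noise. Defaults emulate
#' the ambulance cohort the pipeline is designed for: 560 patients with a
#' STEMI prevalence of 38/560 (~7%) and a near-complete overlap between
#' STEMI and the need of acute PCI.
#'
#' @param n_cases number of records to generate.
#' @param stemi_prevalence probability that a case is a STEMI.
#' @param p_pci_given_stemi P(needs acute PCI | STEMI).
#' @param p_pci_given_nonstemi P(needs acute PCI | no STEMI).
#' @param heart_rate beats per minute.
#' @param sampling_rate sampling frequency, Hz.
#' @param duration record length, seconds.
#' @param wave_amplitudes per-lead Gaussian wave parameters, see
#'   [default_wave_params()].
#' @param st_magnitude_range (min, max) of the injected ST shift, mV. The
#'   draw is clamped upward so every STEMI case clears the diagnostic
#'   threshold of its territory (0.2 mV in V1-V3, 0.1 mV elsewhere) with a
#'   0.05 mV margin.
#' @param noise_sd standard deviation of additive white noise, mV.
#' @param baseline_wander c(amplitude mV, frequency Hz) of a sinusoidal
#'   baseline drift with a random per-lead phase.
#' @param seed integer seed governing the whole cohort.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_cases = 560,
                         stemi_prevalence = 38 / 560,
                         p_pci_given_stemi = 0.9,
                         p_pci_given_nonstemi = 0.01,
                         heart_rate = 60,
                         sampling_rate = 500,
                         duration = 10,
                         wave_amplitudes = default_wave_params(),
                         st_magnitude_range = c(0.15, 0.5),
                         noise_sd = 0.02,
                         baseline_wander = c(0.05, 0.3),
                         seed = 1L) {
  if (n_cases < 1) stopf("'n_cases' must be >= 1")
  assert_fraction(stemi_prevalence, "stemi_prevalence")
  assert_fraction(p_pci_given_stemi, "p_pci_given_stemi")
  assert_fraction(p_pci_given_nonstemi, "p_pci_given_nonstemi")
  if (heart_rate <= 0) stopf("'heart_rate' must be positive")
  if (sampling_rate <= 0) stopf("'sampling_rate' must be positive")
  if (duration < 2) stopf("'duration' must be >= 2 s")
  if (noise_sd < 0) stopf("'noise_sd' must be >= 0")
  if (length(st_magnitude_range) != 2L ||
      st_magnitude_range[1] > st_magnitude_range[2])
    stopf("'st_magnitude_range' must be c(min, max) with min <= max")
  missing_leads <- setdiff(BASIS_LEADS, names(wave_amplitudes))
  if (length(missing_leads))
    stopf("'wave_amplitudes' lacks leads: %s",
          paste(missing_leads, collapse = ", "))
  structure(list(
    n_cases = as.integer(n_cases),
    stemi_prevalence = stemi_prevalence,
    p_pci_given_stemi = p_pci_given_stemi,
    p_pci_given_nonstemi = p_pci_given_nonstemi,
    heart_rate = heart_rate,
    sampling_rate = sampling_rate,
    duration = duration,
    wave_amplitudes = wave_amplitudes,
    st_magnitude_range = st_magnitude_range,
    noise_sd = noise_sd,
    baseline_wander = baseline_wander,
    seed = as.integer(seed)
  ), class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat("Synthetic ECG cohort configuration\n")
  cat(sprintf("  n_cases: %d, STEMI prevalence: %.3f\n",
              x$n_cases, x$stemi_prevalence))
  cat(sprintf("  P(PCI|STEMI) = %.2f, P(PCI|no STEMI) = %.2f\n",
              x$p_pci_given_stemi, x$p_pci_given_nonstemi))
  cat(sprintf("  %g Hz, %g s, %g bpm; noise sd %g mV; ST range [%g, %g] mV\n",
              x$sampling_rate, x$duration, x$heart_rate, x$noise_sd,
              x$st_magnitude_range[1], x$st_magnitude_range[2]))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
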