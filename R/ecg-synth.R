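# Synthetic 12-lead ECG generator.
#
# Eight leads (I, II, V1-V6) are synthesized as sums of Gaussian waves and
# repeated at the configured heart rate; the remaining four limb leads are
# derived exactly through the Einthoven/Goldberger relations, so the linear
# lead identities hold for every generated record. ST elevation is injected
# as a smoothly tapered offset spanning the J point through the end of the
# T wave in the territory's leads.

TERRITORY_LEADS <- list(
  anterior = c("V1", "V2", "V3", "V4"),
  inferior = c("II", "III", "aVF"),
  lateral  = c("I", "aVL", "V5", "V6")
)

# Basis leads the injection is applied to; derived limb leads then pick up
# their share through the lead identities.
TERRITORY_BASIS <- list(
  anterior = c("V1", "V2", "V3", "V4"),
  inferior = "II",
  lateral  = c("I", "V5", "V6")
)

#' Construct a 12-lead ECG record
#'
#' @param samples numeric matrix, 12 rows in the order I, II, III, aVR, aVL,
#'   aVF, V1-V6 (row names are set/checked), voltages in mV.
#' @param sampling_rate sampling frequency in Hz.
#' @param record_id opaque identifier.
#' @param fiducial_hint optional list with the generator's ground-truth beat
#'   timing: `qrs_on`, `j_point`, `t_end` (seconds from beat onset) and
#'   `beat_period` (seconds).
#' @return object of class `ecg_record`.
#' @export
ecg_record <- function(samples, sampling_rate, record_id = "rec",
                       fiducial_hint = NULL) {
  if (!is.matrix(samples) || nrow(samples) != 12L)
    stopf("'samples' must be a 12-row matrix (one row per lead)")
  if (is.null(rownames(samples))) {
    rownames(samples) <- LEAD_NAMES
  } else if (!identical(rownames(samples), LEAD_NAMES)) {
    stopf("lead rows must be ordered %s", paste(LEAD_NAMES, collapse = ", "))
  }
  if (sampling_rate <= 0) stopf("'sampling_rate' must be positive")
  if (ncol(samples) < 2 * sampling_rate)
    stopf("record must be at least 2 s long")
  if (!all(is.finite(samples))) stopf("all voltages must be finite")
  structure(list(
    lead_names = LEAD_NAMES,
    samples = samples,
    sampling_rate = sampling_rate,
    record_id = as.character(record_id),
    fiducial_hint = fiducial_hint
  ), class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record %s: 12 leads x %d samples @ %g Hz (%.1f s)>\n",
              x$record_id, ncol(x$samples), x$sampling_rate,
              ncol(x$samples) / x$sampling_rate))
  invisible(x)
}

#' Single-beat waveform template from Gaussian wave components
#'
#' Sums the five Gaussian components (P, Q, R, S, T) of one lead on a
#' uniform time grid covering one beat.
#'
#' @param wave_params 5x3 matrix with rows P, Q, R, S, T and columns
#'   amp (mV), center (s), width (s).
#' @param sampling_rate Hz.
#' @param beat_duration beat length in seconds; must cover all wave centers.
#' @return numeric vector of voltages (mV), length
#'   `round(beat_duration * sampling_rate)`.
#' @export
synth_beat_template <- function(wave_params, sampling_rate, beat_duration) {
  if (sampling_rate <= 0) stopf("'sampling_rate' must be positive")
  if (any(wave_params[, "width"] <= 0)) stopf("wave widths must be positive")
  if (beat_duration < max(wave_params[, "center"]))
    stopf("'beat_duration' must cover all wave centers")
  n <- round(beat_duration * sampling_rate)
  t <- (seq_len(n) - 1) / sampling_rate
  v <- numeric(n)
  for (w in seq_len(nrow(wave_params))) {
    a <- wave_params[w, "amp"]
    if (a == 0) next
    v <- v + a * exp(-((t - wave_params[w, "center"])^2) /
                       (2 * wave_params[w, "width"]^2))
  }
  v
}

#' Derive the remaining limb leads from leads I and II
#'
#' Applies the Einthoven and Goldberger relations: III = II - I,
#' aVR = -(I + II)/2, aVL = I - II/2, aVF = II - I/2.
#'
#' @param lead_I,lead_II numeric vectors of equal length (mV).
#' @return named list with elements III, aVR, aVL, aVF.
#' @export
derive_limb_leads <- function(lead_I, lead_II) {
  if (length(lead_I) != length(lead_II))
    stopf("leads I and II must have equal length")
  list(
    III = lead_II - lead_I,
    aVR = -(lead_I + lead_II) / 2,
    aVL = lead_I - lead_II / 2,
    aVF = lead_II - lead_I / 2
  )
}

# Per-sample ST offset profile for a whole record: within each beat, a
# raised-cosine ramp over `ramp` seconds ending at the J point, a plateau of
# height `magnitude` through t_end, and a raised-cosine decay after it.
st_offset_profile <- function(n_samples, sampling_rate, beat_period,
                              j_point, t_end, magnitude, ramp = 0.02) {
  t <- (seq_len(n_samples) - 1) / sampling_rate
  phase <- t %% beat_period
  off <- numeric(n_samples)
  up <- phase >= (j_point - ramp) & phase < j_point
  off[up] <- magnitude * 0.5 * (1 - cos(pi * (phase[up] - j_point + ramp) / ramp))
  plateau <- phase >= j_point & phase <= t_end
  off[plateau] <- magnitude
  down <- phase > t_end & phase <= (t_end + ramp)
  off[down] <- magnitude * 0.5 * (1 + cos(pi * (phase[down] - t_end) / ramp))
  off
}

#' Inject ST-segment elevation into a record's infarct territory
#'
#' Adds a smoothly tapered voltage offset of peak size `magnitude` from the
#' QRS offset (J point) through the end of the T wave in every beat, in the
#' leads of the requested territory. The offset is applied to the
#' independently synthesized leads (I, II, V1-V6) and the derived limb leads
#' are recomputed, so the Einthoven/Goldberger identities hold exactly
#' afterwards; inferior injection therefore also produces the physiological
#' reciprocal depression in aVL.
#'
#' @param record an [ecg_record()].
#' @param territory one of "anterior", "inferior", "lateral".
#' @param magnitude peak ST shift in mV, >= 0.
#' @param fiducial_hint beat timing (see [ecg_record()]); defaults to the
#'   hint stored on the record.
#' @return the modified `ecg_record`.
#' @export
inject_st_elevation <- function(record, territory, magnitude,
                                fiducial_hint = record$fiducial_hint) {
  if (!territory %in% names(TERRITORY_LEADS))
    stopf("unknown territory '%s'", territory)
  if (magnitude < 0) stopf("'magnitude' must be >= 0")
  if (magnitude == 0) return(record)
  if (is.null(fiducial_hint))
    stopf("record carries no fiducial hint; supply 'fiducial_hint'")
  prof <- st_offset_profile(ncol(record$samples), record$sampling_rate,
                            fiducial_hint$beat_period,
                            fiducial_hint$j_point, fiducial_hint$t_end,
                            magnitude)
  s <- record$samples
  for (lead in TERRITORY_BASIS[[territory]])
    s[lead, ] <- s[lead, ] + prof
  d <- derive_limb_leads(s["I", ], s["II", ])
  s["III", ] <- d$III; s["aVR", ] <- d$aVR
  s["aVL", ] <- d$aVL; s["aVF", ] <- d$aVF
  record$samples <- s
  record
}

# Effective per-lead plateau offsets implied by injecting `magnitude` into
# the territory's basis leads, propagated through the lead identities.
effective_st_offsets <- function(territory, magnitude) {
  off <- stats::setNames(numeric(12), LEAD_NAMES)
  if (territory == "none" || magnitude == 0) return(off)
  off[TERRITORY_BASIS[[territory]]] <- magnitude
  off["III"] <- off["II"] - off["I"]
  off["aVR"] <- -(off["I"] + off["II"]) / 2
  off["aVL"] <- off["I"] - off["II"] / 2
  off["aVF"] <- off["II"] - off["I"] / 2
  off
}

# Diagnostic ST threshold (mV) that the injected magnitude must clear for
# the territory's defining lead pair: 0.2 mV when V1-V3 are involved,
# 0.1 mV otherwise (1 mm = 0.1 mV at standard calibration).
territory_threshold <- function(territory) {
  if (territory == "anterior") 0.2 else 0.1
}

#' Generate one labeled synthetic case
#'
#' Draws the STEMI status from the configured prevalence; for STEMI cases
#' draws a territory (uniformly among anterior/inferior/lateral) and an ST
#' magnitude large enough to satisfy the diagnostic criterion, injects the
#' elevation, then adds baseline wander and white noise. The needs-acute-PCI
#' label is drawn from the conditional probabilities. Fully reproducible for
#' a fixed (config seed, case seed) pair.
#'
#' @param config a [synth_config()].
#' @param case_seed integer stream index of this case.
#' @return list with elements `record` ([ecg_record()]) and `label` (list
#'   with `stemi`, `needs_acute_pci`, `territory`, `st_offsets`).
#' @export
generate_case <- function(config, case_seed) {
  set.seed(mix_seed(config$seed, case_seed))
  fs <- config$sampling_rate
  beat <- 60 / config$heart_rate
  n <- round(config$duration * fs)
  n_beats <- ceiling(config$duration / beat)

  is_stemi <- stats::runif(1) < config$stemi_prevalence
  if (is_stemi) {
    territory <- sample(names(TERRITORY_LEADS), 1)
    m <- stats::runif(1, config$st_magnitude_range[1],
                      config$st_magnitude_range[2])
    m <- max(m, territory_threshold(territory) + 0.05)
  } else {
    territory <- "none"
    m <- 0
  }
  p_pci <- if (is_stemi) config$p_pci_given_stemi else config$p_pci_given_nonstemi
  needs_pci <- stats::runif(1) < p_pci

  # ground-truth beat timing shared by all leads
  wp <- config$wave_amplitudes[[1]]
  qrs_on <- wp["Q", "center"] - 2 * wp["Q", "width"]
  j_point <- wp["S", "center"] + 2 * wp["S", "width"]
  t_end <- wp["T", "center"] + 2.5 * wp["T", "width"]
  hint <- list(qrs_on = qrs_on, j_point = j_point, t_end = t_end,
               beat_period = beat)

  basis <- matrix(0, length(BASIS_LEADS), n,
                  dimnames = list(BASIS_LEADS, NULL))
  for (lead in BASIS_LEADS) {
    tmpl <- synth_beat_template(config$wave_amplitudes[[lead]], fs, beat)
    basis[lead, ] <- rep_len(tmpl, n)
  }
  if (m > 0) {
    prof <- st_offset_profile(n, fs, beat, j_point, t_end, m)
    for (lead in TERRITORY_BASIS[[territory]])
      basis[lead, ] <- basis[lead, ] + prof
  }
  t_grid <- (seq_len(n) - 1) / fs
  bw_amp <- config$baseline_wander[1]
  bw_freq <- config$baseline_wander[2]
  for (lead in BASIS_LEADS) {
    if (bw_amp > 0)
      basis[lead, ] <- basis[lead, ] +
        bw_amp * sin(2 * pi * bw_freq * t_grid + stats::runif(1, 0, 2 * pi))
    if (config$noise_sd > 0)
      basis[lead, ] <- basis[lead, ] + stats::rnorm(n, 0, config$noise_sd)
  }

  d <- derive_limb_leads(basis["I", ], basis["II", ])
  samples <- rbind(I = basis["I", ], II = basis["II", ], III = d$III,
                   aVR = d$aVR, aVL = d$aVL, aVF = d$aVF,
                   basis[c("V1", "V2", "V3", "V4", "V5", "V6"), ])
  rec <- ecg_record(samples, fs,
                    record_id = sprintf("case%05d", case_seed),
                    fiducial_hint = hint)
  label <- list(stemi = is_stemi, needs_acute_pci = needs_pci,
                territory = territory,
                st_offsets = effective_st_offsets(territory, m))
  list(record = rec, label = label)
}

#' Generate a labeled synthetic cohort
#'
#' @param config a [synth_config()].
#' @return list of class `ecg_cohort`; each element as in [generate_case()].
#' @export
generate_cohort <- function(config) {
  cohort <- lapply(seq_len(config$n_cases),
                   function(i) generate_case(config, i))
  class(cohort) <- "ecg_cohort"
  cohort
}

#' Cohort labels as a data frame
#'
#' @param cohort an `ecg_cohort` (or plain list of case lists).
#' @return data.frame with record_id, stemi, needs_acute_pci, territory.
#' @export
cohort_labels <- function(cohort) {
  data.frame(
    record_id = vapply(cohort, function(x) x$record$record_id, ""),
    stemi = vapply(cohort, function(x) x$label$stemi, NA),
    needs_acute_pci = vapply(cohort, function(x) x$label$needs_acute_pci, NA),
    territory = vapply(cohort, function(x) x$label$territory, ""),
    stringsAsFactors = FALSE
  )
}

#' @export
print.ecg_cohort <- function(x, ...) {
  lab <- cohort_labels(x)
  cat(sprintf("<ecg_cohort: %d records, %d STEMI (%.1f%%), %d need acute PCI>\n",
              nrow(lab), sum(lab$stemi), 100 * mean(lab$stemi),
              sum(lab$needs_acute_pci)))
  invisible(x)
}
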