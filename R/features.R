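# Fiducial-point detection and per-lead measurement.
#
# One global set of time fiducials per record is computed on the
# root-mean-square (RMS) signal across the 12 leads: the RMS maximum of each
# beat marks the R peak, QRS onset/offset are found by scanning outward from
# the R peak until the RMS slope stays below 10% of its beat maximum for at
# least 8 ms, and T end is the return of the RMS to near its baseline level
# after the T peak. All amplitude measures are taken relative to a per-lead
# isoelectric baseline estimated from the PR segment.

MEASURE_NAMES <- c("q_amp", "r_amp", "s_amp", "qrs_area", "qrs_duration",
                   "t_pos", "t_neg", paste0("st", 1:6))

# ST sampling positions after the J point, in seconds.
ST_OFFSETS_S <- c(0, 16, 32, 48, 64, 80) / 1000

#' Detect beat fiducial points on the cross-lead RMS signal
#'
#' @param record an [ecg_record()].
#' @return object of class `fiducial_points`: per-beat integer vectors
#'   `r_peak`, `qrs_on`, `qrs_off`, `t_end` (sample indices), plus
#'   `sampling_rate` and `n_samples`. Beats too close to the record edges to
#'   be fully measurable are dropped.
#' @export
detect_fiducials <- function(record) {
  fs <- record$sampling_rate
  s <- record$samples
  n <- ncol(s)
  rms <- sqrt(colMeans(s^2))
  if (max(rms) < 0.2)
    stopf("no beat found in record %s (RMS maximum %.3f mV < 0.2 mV)",
          record$record_id, max(rms))

  # R peaks: local RMS maxima above half the global maximum, separated by
  # at least 300 ms.
  min_sep <- round(0.3 * fs)
  cand <- which(rms > 0.5 * max(rms))
  cand <- cand[order(rms[cand], decreasing = TRUE)]
  r_peaks <- integer(0)
  for (i in cand)
    if (!length(r_peaks) || all(abs(r_peaks - i) >= min_sep))
      r_peaks <- c(r_peaks, i)
  r_peaks <- sort(r_peaks)

  slope <- c(0, diff(rms)) * fs
  k8 <- max(1L, round(0.008 * fs))   # 8 ms of sustained quiescence
  half <- round(0.12 * fs)           # QRS search half-width

  scan_edge <- function(r, dir) {
    win <- max(1, r - half):min(n, r + half)
    smax <- max(abs(slope[win]))
    run <- 0L
    i <- r + dir
    edge <- if (dir < 0) max(1, r - half) else min(n, r + half)
    while (i >= 1 && i <= n) {
      if (abs(slope[i]) < 0.1 * smax) {
        run <- run + 1L
        if (run >= k8) return(i - dir * (k8 - 1L))
      } else run <- 0L
      if (abs(i - r) > 2 * half) break
      i <- i + dir
    }
    edge
  }

  qrs_on <- as.integer(vapply(r_peaks, scan_edge, 0, dir = -1))
  qrs_off <- as.integer(vapply(r_peaks, scan_edge, 0, dir = +1))

  rms_base <- as.numeric(stats::quantile(rms, 0.1))
  t_end <- integer(length(r_peaks))
  for (b in seq_along(r_peaks)) {
    limit <- if (b < length(r_peaks)) r_peaks[b + 1] - round(0.05 * fs) else n
    t_win <- (qrs_off[b] + round(0.04 * fs)):min(limit, n)
    if (length(t_win) < 2) { t_end[b] <- limit; next }
    t_peak <- t_win[which.max(rms[t_win])]
    after <- t_peak:min(limit, n)
    back <- after[rms[after] <= rms_base + 0.05]
    t_end[b] <- if (length(back)) back[1] else limit
  }

  # keep only fully measurable beats (PR window and J + 80 ms in range)
  lead_in <- round(0.06 * fs)
  keep <- qrs_on - lead_in >= 1 & qrs_off + round(0.08 * fs) <= n &
    t_end > qrs_off
  if (!any(keep))
    stopf("record %s: no fully measurable beat", record$record_id)
  structure(list(r_peak = r_peaks[keep], qrs_on = qrs_on[keep],
                 qrs_off = qrs_off[keep], t_end = t_end[keep],
                 sampling_rate = fs, n_samples = n),
            class = "fiducial_points")
}

#' Per-lead isoelectric baseline from the PR segment
#'
#' Mean voltage over a 40 ms window ending 10 ms before QRS onset, averaged
#' across beats.
#'
#' @param lead numeric vector of one lead's voltages (mV).
#' @param fiducials a `fiducial_points` object.
#' @return baseline voltage in mV.
#' @export
estimate_baseline <- function(lead, fiducials) {
  fs <- fiducials$sampling_rate
  w40 <- round(0.04 * fs)
  w10 <- round(0.01 * fs)
  means <- vapply(fiducials$qrs_on, function(on) {
    to <- on - w10
    from <- to - w40 + 1
    if (from < 1) stopf("PR window out of range at QRS onset index %d", on)
    mean(lead[from:to])
  }, 0)
  mean(means)
}

#' The 13 measurements of one lead
#'
#' Relative to the PR baseline and averaged over beats: Q, R and S
#' amplitudes (unsigned depths/heights, 0 when the deflection is absent),
#' QRS area (mV*ms), QRS duration (ms), positive and negative T amplitudes,
#' and the signed ST amplitude at six positions J + 0/16/32/48/64/80 ms.
#'
#' @param lead numeric vector of one lead's voltages (mV).
#' @param fiducials a `fiducial_points` object.
#' @return named numeric vector of length 13 (see `MEASURE_NAMES` order:
#'   q_amp, r_amp, s_amp, qrs_area, qrs_duration, t_pos, t_neg, st1-st6).
#' @export
measure_lead <- function(lead, fiducials) {
  fs <- fiducials$sampling_rate
  dt_ms <- 1000 / fs
  base <- estimate_baseline(lead, fiducials)
  v <- lead - base
  st_idx_off <- round(ST_OFFSETS_S * fs)
  clipped <- FALSE

  per_beat <- vapply(seq_along(fiducials$r_peak), function(b) {
    on <- fiducials$qrs_on[b]; off <- fiducials$qrs_off[b]
    r <- fiducials$r_peak[b]; te <- fiducials$t_end[b]
    qrs <- v[on:off]
    r_amp <- max(0, max(qrs))
    pre <- if (r > on) v[on:(r - 1)] else numeric(0)
    q_amp <- if (length(pre)) max(0, -min(pre)) else 0
    post <- if (r < off) v[(r + 1):off] else numeric(0)
    s_amp <- if (length(post)) max(0, -min(post)) else 0
    qrs_area <- sum(abs(qrs)) * dt_ms
    qrs_duration <- (off - on) * dt_ms
    t_win <- if (te > off) v[(off + 1):te] else numeric(0)
    t_pos <- if (length(t_win)) max(0, max(t_win)) else 0
    t_neg <- if (length(t_win)) max(0, -min(t_win)) else 0
    st_idx <- off + st_idx_off
    if (any(st_idx > fiducials$n_samples)) {
      clipped <<- TRUE
      st_idx <- pmin(st_idx, fiducials$n_samples)
    }
    st <- v[st_idx]
    c(q_amp, r_amp, s_amp, qrs_area, qrs_duration, t_pos, t_neg, st)
  }, numeric(13))

  if (clipped)
    warnf("ST sampling positions clipped to the last valid sample")
  stats::setNames(rowMeans(per_beat), MEASURE_NAMES)
}

#' Extract the 156-variable feature vector of one record
#'
#' Concatenates [measure_lead()] over the 12 leads in the fixed order I, II,
#' III, aVR, aVL, aVF, V1-V6 (13 measures per lead, 12 x 13 = 156). Names
#' follow the `<lead>_<measure>` convention (e.g. `V2_st1`).
#'
#' @param record an [ecg_record()].
#' @param fiducials optional precomputed `fiducial_points`.
#' @return named numeric vector of length 156.
#' @export
extract_features <- function(record, fiducials = NULL) {
  if (is.null(fiducials)) {
    fiducials <- tryCatch(detect_fiducials(record), error = function(e)
      stopf("feature extraction failed for record %s: %s",
            record$record_id, conditionMessage(e)))
  }
  out <- unlist(lapply(LEAD_NAMES, function(ld) {
    m <- measure_lead(record$samples[ld, ], fiducials)
    stats::setNames(m, paste(ld, MEASURE_NAMES, sep = "_"))
  }))
  stopifnot(length(out) == 156L)
  out
}

#' Feature matrix of a cohort
#'
#' @param cohort an `ecg_cohort`.
#' @return numeric matrix, one row per record (row names = record ids),
#'   156 columns.
#' @export
extract_feature_matrix <- function(cohort) {
  rows <- lapply(cohort, function(case) extract_features(case$record))
  X <- do.call(rbind, rows)
  rownames(X) <- vapply(cohort, function(case) case$record$record_id, "")
  X
}

#' Write / read a feature matrix as CSV
#'
#' One row per record, `record_id` first, then the 156 named features.
#'
#' @param X feature matrix with row names.
#' @param path CSV file path.
#' @return `read_feature_matrix` returns the matrix with record-id row
#'   names.
#' @export
write_feature_matrix <- function(X, path) {
  df <- data.frame(record_id = rownames(X), X, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  X <- as.matrix(df[, -1, drop = FALSE])
  rownames(X) <- df$record_id
  X
}

# Lead pairs counted as "adjacent" for the diagnostic rule: consecutive
# precordial pairs plus any pair within the anatomical groups
# {II, III, aVF}, {I, aVL} and {V5, V6, I, aVL}.
adjacent_pairs <- function() {
  pairs <- list(c("V1", "V2"), c("V2", "V3"), c("V3", "V4"),
                c("V4", "V5"), c("V5", "V6"))
  for (grp in list(c("II", "III", "aVF"), c("I", "aVL"),
                   c("V5", "V6", "I", "aVL")))
    pairs <- c(pairs, utils::combn(grp, 2, simplify = FALSE))
  unique(lapply(pairs, sort))
}

#' Rule-based ST-elevation criterion
#'
#' TRUE iff at least two adjacent leads each show an ST elevation at the J
#' point of at least 2 mm (0.2 mV) in V1-V3 and at least 1 mm (0.1 mV) in
#' all other leads.
#'
#' @param st_by_lead named numeric vector with the J-point ST amplitude of
#'   all 12 leads, in mV.
#' @return logical.
#' @export
stemi_criteria <- function(st_by_lead) {
  missing_leads <- setdiff(LEAD_NAMES, names(st_by_lead))
  if (length(missing_leads))
    stopf("missing leads: %s", paste(missing_leads, collapse = ", "))
  thr <- ifelse(LEAD_NAMES %in% c("V1", "V2", "V3"), 0.2, 0.1)
  names(thr) <- LEAD_NAMES
  meets <- st_by_lead[LEAD_NAMES] >= thr
  any(vapply(adjacent_pairs(), function(p) meets[p[1]] && meets[p[2]], NA))
}

#' J-point ST amplitudes of all 12 leads from a feature vector
#'
#' Convenience accessor pulling the `<lead>_st1` entries of
#' [extract_features()] output.
#'
#' @param features named numeric vector of length 156.
#' @return named numeric vector of 12 J-point ST values (mV).
#' @export
st_at_j <- function(features) {
  stats::setNames(features[paste0(LEAD_NAMES, "_st1")], LEAD_NAMES)
}
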