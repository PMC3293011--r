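# Plain-text persistence of labeled cohorts.
#
# CSV dialect: one file per record named <record_id>.csv with header
# `lead,t0,dt,unit=mV` and one row per lead (lead name, start time, sample
# interval, then voltages printed with 6 decimals), plus a sidecar
# labels.csv with record_id,stemi,needs_acute_pci,territory.
# WFDB-style dialect: a text header <record_id>.hea (record line + one line
# per lead) and a whitespace-separated sample matrix <record_id>.txt.

#' Write a cohort to disk
#'
#' @param cohort an `ecg_cohort` (list of record+label pairs).
#' @param path directory to write into (created if needed).
#' @param format `"csv"` (default) or `"wfdb"` (plain-text header+signal
#'   pair).
#' @return invisibly, the vector of files written.
#' @export
write_records <- function(cohort, path, format = c("csv", "wfdb")) {
  format <- match.arg(format)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (case in cohort) {
    rec <- case$record
    if (format == "csv") {
      f <- file.path(path, paste0(rec$record_id, ".csv"))
      dt <- 1 / rec$sampling_rate
      lines <- c("lead,t0,dt,unit=mV",
                 vapply(seq_len(12), function(i) {
                   paste(c(rec$lead_names[i], "0", format(dt, digits = 12),
                           sprintf("%.6f", rec$samples[i, ])),
                         collapse = ",")
                 }, ""))
      writeLines(lines, f)
      files <- c(files, f)
    } else {
      hea <- file.path(path, paste0(rec$record_id, ".hea"))
      dat <- file.path(path, paste0(rec$record_id, ".txt"))
      writeLines(c(sprintf("%s 12 %g %d", rec$record_id, rec$sampling_rate,
                           ncol(rec$samples)),
                   rec$lead_names), hea)
      utils::write.table(t(signif(rec$samples, 7)), dat,
                         row.names = FALSE, col.names = FALSE)
      files <- c(files, hea, dat)
    }
  }
  lab <- cohort_labels(cohort)
  labf <- file.path(path, "labels.csv")
  utils::write.csv(lab, labf, row.names = FALSE)
  invisible(c(files, labf))
}

read_one_csv <- function(f) {
  lines <- readLines(f)
  id <- sub("\\.csv$", "", basename(f))
  if (length(lines) < 13)
    stopf("record %s: expected 12 lead rows, found %d (file truncated)",
          id, length(lines) - 1)
  if (!startsWith(lines[1], "lead,t0,dt"))
    stopf("record %s: line 1: malformed header '%s'", id, lines[1])
  samples <- NULL
  dt <- NA_real_
  for (i in 2:13) {
    parts <- strsplit(lines[i], ",", fixed = TRUE)[[1]]
    lead <- parts[1]
    if (lead != LEAD_NAMES[i - 1])
      stopf("record %s: line %d: expected lead %s, found '%s'",
            id, i, LEAD_NAMES[i - 1], lead)
    v <- suppressWarnings(as.numeric(parts[-(1:3)]))
    if (anyNA(v))
      stopf("record %s: line %d: non-numeric voltage", id, i)
    dt <- as.numeric(parts[3])
    if (is.null(samples))
      samples <- matrix(NA_real_, 12, length(v), dimnames = list(LEAD_NAMES, NULL))
    if (length(v) != ncol(samples))
      stopf("record %s: line %d: ragged lead lengths", id, i)
    samples[i - 1, ] <- v
  }
  ecg_record(samples, sampling_rate = 1 / dt, record_id = id)
}

read_one_wfdb <- function(hea) {
  id <- sub("\\.hea$", "", basename(hea))
  h <- readLines(hea)
  if (length(h) < 13) stopf("record %s: malformed header (need 13 lines)", id)
  fields <- strsplit(h[1], "\\s+")[[1]]
  fs <- as.numeric(fields[3])
  leads <- h[2:13]
  if (!identical(leads, LEAD_NAMES))
    stopf("record %s: header lead order differs from the standard 12 leads", id)
  m <- as.matrix(utils::read.table(file.path(dirname(hea), paste0(id, ".txt"))))
  samples <- t(m)
  dimnames(samples) <- list(LEAD_NAMES, NULL)
  ecg_record(samples, sampling_rate = fs, record_id = id)
}

#' Read a cohort written by [write_records()]
#'
#' Labels are taken from the sidecar `labels.csv`; records without a label
#' row get NA labels with a warning.
#'
#' @param path directory containing the record files.
#' @return an `ecg_cohort`.
#' @export
read_records <- function(path) {
  csvs <- setdiff(list.files(path, pattern = "\\.csv$", full.names = TRUE),
                  file.path(path, "labels.csv"))
  heas <- list.files(path, pattern = "\\.hea$", full.names = TRUE)
  if (length(csvs) == 0 && length(heas) == 0) {
    warnf("no record files found in '%s'; returning an empty cohort", path)
    return(structure(list(), class = "ecg_cohort"))
  }
  recs <- c(lapply(csvs, read_one_csv), lapply(heas, read_one_wfdb))
  labf <- file.path(path, "labels.csv")
  lab <- if (file.exists(labf)) utils::read.csv(labf) else NULL
  cohort <- lapply(recs, function(rec) {
    label <- list(stemi = NA, needs_acute_pci = NA, territory = NA_character_)
    if (!is.null(lab) && rec$record_id %in% lab$record_id) {
      row <- lab[lab$record_id == rec$record_id, , drop = FALSE]
      label <- list(stemi = as.logical(row$stemi),
                    needs_acute_pci = as.logical(row$needs_acute_pci),
                    territory = as.character(row$territory))
    } else {
      warnf("record %s has no row in labels.csv", rec$record_id)
    }
    list(record = rec, label = label)
  })
  class(cohort) <- "ecg_cohort"
  cohort
}
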