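#' Write / read an EEG recording as delimited text
#'
#' Plain-text channel-by-sample format: `#key: value` header lines carrying
#' the sampling and labelling metadata, then one tab-separated row per
#' channel (channel label first). Round-trips an `eeg_recording` losslessly
#' up to the stated numeric precision.
#'
#' @param rec An `eeg_recording`.
#' @param path Output file path.
#' @param digits Significant digits written (default 8).
#' @return `path`, invisibly.
#' @export
write_eeg_txt <- function(rec, path, digits = 8) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#fs: %.10g", rec$fs), con)
  writeLines(sprintf("#subject_id: %s", rec$subject_id), con)
  writeLines(sprintf("#group: %s", rec$group), con)
  writeLines(sprintf("#phase: %s", rec$phase), con)
  for (i in seq_len(nrow(rec$data)))
    writeLines(paste(c(rec$channel_labels[i],
                       formatC(rec$data[i, ], digits = digits, format = "g")),
                     collapse = "\t"), con)
  invisible(path)
}

#' @rdname write_eeg_txt
#' @export
read_eeg_txt <- function(path) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "#")
  hdr <- lines[is_hdr]
  meta <- list()
  for (h in hdr) {
    kv <- regmatches(h, regexec("^#([^:]+): ?(.*)$", h))[[1]]
    if (length(kv) == 3L) meta[[kv[2]]] <- kv[3]
  }
  if (is.null(meta$fs)) stop_invalid("missing '#fs:' header in ", path)
  body <- strsplit(lines[!is_hdr], "\t", fixed = TRUE)
  labels <- vapply(body, `[`, character(1), 1L)
  data <- do.call(rbind, lapply(body, function(x) as.numeric(x[-1L])))
  eeg_recording(data, fs = as.numeric(meta$fs), channel_labels = labels,
                subject_id = meta$subject_id %||% NA_character_,
                group = meta$group %||% NA_character_,
                phase = meta$phase %||% NA_character_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a cohort table as CSV
#'
#' Column dictionary: `subject_id` (label); `group`
#' (propofol/esketamine); `age` (years); `sex` (M/F); `etiology` (TBI/CVD);
#' `disease_duration` (months); `baseline_state`, `state_3mo` (UWS, MCS-,
#' MCS+, EMCS); `crsr_baseline` (0-23); `surgical_time`, `recovery_time`
#' (minutes); `norepinephrine` (yes/no); `improved` (TRUE/FALSE).
#'
#' @param cohort A `cohort_table`.
#' @param path CSV path.
#' @return `path` invisibly (write) or the `cohort_table` (read).
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  dat <- utils::read.csv(path, stringsAsFactors = FALSE)
  dat$group <- factor(dat$group, levels = c("propofol", "esketamine"))
  dat$etiology <- factor(dat$etiology, levels = c("CVD", "TBI"))
  dat$improved <- as.logical(dat$improved)
  class(dat) <- c("cohort_table", "data.frame")
  dat
}
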