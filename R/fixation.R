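# Fixation metrics: raw gaze samples -> participant x AoI percentage table,
# plus the availability exclusion rule.
#
# "Fixation time" here is raw-sample dwell at the device rate: no velocity
# filtering or fixation-event detection is applied, and the denominator of
# every percentage is the FULL scheduled stimulus duration (invalid samples
# included). That is why per-stimulus columns need not sum to 100 among
# valid regions: the missing share is tracker dropout.

validate_stream <- function(stream, battery, participant = NULL) {
  nsamp <- stimulus_samples(battery)
  have <- split(stream, stream$stimulus_id)
  missing <- setdiff(names(nsamp), names(have))
  if (length(missing))
    gf_stop(sprintf("stream%s is missing stimuli: %s",
                    if (is.null(participant)) "" else paste0(" for ", participant),
                    paste(missing, collapse = ", ")),
            "gf_stream_error")
  for (sid in names(nsamp)) {
    s <- have[[sid]]
    if (nrow(s) != nsamp[[sid]])
      gf_stop(sprintf("stimulus '%s': expected %d samples, got %d",
                      sid, nsamp[[sid]], nrow(s)), "gf_stream_error")
    if (is.unsorted(s$t_ms, strictly = TRUE))
      gf_stop(sprintf("stimulus '%s': timestamps not strictly increasing", sid),
              "gf_stream_error")
  }
  invisible(stream)
}

#' Session availability of a gaze stream
#'
#' Percentage of all scheduled samples, across every battery stimulus, in
#' which the tracker reported a valid eye position.
#'
#' @param stream one participant's gaze samples (`stimulus_id`, `t_ms`,
#'   `valid`, ...).
#' @param battery a `gf_battery`.
#' @return availability in percent.
#' @export
compute_availability <- function(stream, battery) {
  validate_stream(stream, battery)
  100 * sum(stream$valid == 1) / nrow(stream)
}

#' One participant's fixation record
#'
#' Per (stimulus, AoI): `100 * valid samples inside the AoI rectangle /
#' scheduled samples of the stimulus`. Also reports the valid out-of-AoI
#' share per stimulus and the session availability.
#'
#' @param stream one participant's gaze samples.
#' @param battery a `gf_battery`.
#' @return one-row data.frame: `participant_id`, `availability`, one column
#'   per item (`"A.eyes"`, ...) and per stimulus out share (`"A.out"`, ...).
#' @export
compute_fixation_record <- function(stream, battery) {
  pid <- unique(stream$participant_id)
  if (length(pid) != 1L)
    gf_stop("compute_fixation_record expects a single participant's stream",
            "gf_stream_error")
  validate_stream(stream, battery, pid)
  by_stim <- split(stream, stream$stimulus_id)
  vals <- list(participant_id = pid,
               availability = 100 * sum(stream$valid == 1) / nrow(stream))
  for (st in battery$stimuli) {
    s <- by_stim[[st$id]]
    n <- nrow(s)
    valid <- s$valid == 1
    in_any <- rep(FALSE, n)
    for (a in st$aois) {
      inside <- valid & !is.na(s$x_px) & !is.na(s$y_px) &
        s$x_px >= a$rect[1] & s$x_px < a$rect[3] &
        s$y_px >= a$rect[2] & s$y_px < a$rect[4]
      vals[[paste0(st$id, ".", a$id)]] <- 100 * sum(inside) / n
      in_any <- in_any | inside
    }
    vals[[paste0(st$id, ".out")]] <- 100 * sum(valid & !in_any) / n
  }
  as.data.frame(vals, check.names = FALSE, stringsAsFactors = FALSE)
}

fixation_table_from_records <- function(records, battery, threshold = 80) {
  keep <- records$availability >= threshold
  structure(list(
    included = records[keep, , drop = FALSE],
    excluded = records[!keep, c("participant_id", "availability"), drop = FALSE],
    threshold = threshold,
    items = battery_items(battery)$item
  ), class = "gf_fixation_table")
}

#' Fixation table with availability exclusion
#'
#' Converts a multi-participant gaze sample table into one fixation record
#' per participant and partitions the cohort by the availability rule:
#' participants whose availability is strictly below `threshold` percent
#' are routed to `excluded`.
#'
#' @param gaze gaze samples for one or more participants.
#' @param battery a `gf_battery`.
#' @param threshold exclusion threshold in percent (default 80; strict `<`
#'   exclusion).
#' @return A `gf_fixation_table`: list with `included` (fixation records),
#'   `excluded` (`participant_id`, `availability`), `threshold`, `items`.
#' @export
compute_fixation_table <- function(gaze, battery, threshold = 80) {
  streams <- split(gaze, gaze$participant_id)
  # keep first-appearance order rather than alphabetical
  streams <- streams[unique(gaze$participant_id)]
  records <- do.call(rbind, lapply(streams, compute_fixation_record,
                                   battery = battery))
  rownames(records) <- NULL
  fixation_table_from_records(records, battery, threshold)
}

#' @export
print.gf_fixation_table <- function(x, ...) {
  cat(sprintf("<gf_fixation_table> %d included, %d excluded (availability < %g%%)\n",
              nrow(x$included), nrow(x$excluded), x$threshold))
  invisible(x)
}

#' Write a fixation table to CSV
#'
#' Percentages are written at 0.1 precision; one row per included
#' participant, excluded participants in a companion file when requested.
#'
#' @param fixation a `gf_fixation_table`.
#' @param path output CSV path for included records.
#' @param excluded_path optional CSV path for the exclusion list.
#' @return `path`, invisibly.
#' @export
write_fixation_csv <- function(fixation, path, excluded_path = NULL) {
  inc <- fixation$included
  num <- vapply(inc, is.numeric, TRUE)
  inc[num] <- lapply(inc[num], function(v) sprintf("%.1f", v))
  utils::write.csv(inc, path, row.names = FALSE, quote = FALSE)
  if (!is.null(excluded_path)) {
    exc <- fixation$excluded
    exc$availability <- sprintf("%.1f", exc$availability)
    utils::write.csv(exc, excluded_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
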