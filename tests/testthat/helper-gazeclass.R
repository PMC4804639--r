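# Shared fixtures built in code.

# A miniature two-stimulus battery for fast exact-arithmetic tests:
# 5 s face-like stimulus with two AoIs and a 2 s single-AoI stimulus.
tiny_battery <- function(rate = 10L) {
  structure(list(
    screen = screen_spec(100L, 100L, rate),
    stimuli = list(
      gazeclass:::stimulus_spec("A", "face", 5, list(
        gazeclass:::aoi_region("eyes", "aoi1", c(10, 10, 50, 40), "asd_lower"),
        gazeclass:::aoi_region("mouth", "aoi2", c(10, 60, 50, 90), "asd_higher"))),
      gazeclass:::stimulus_spec("B", "window", 2, list(
        gazeclass:::aoi_region("geometry", "aoi1", c(60, 60, 90, 90), "asd_higher")))
    )), class = "gf_battery")
}

# Deterministic stream for one participant on a battery: per stimulus, the
# first `n_aoi[[stim]][k]` samples sit at the centre of AoI k, the next
# `n_out` in a known out-of-AoI spot, the last `n_invalid` are invalid.
make_stream <- function(pid, battery, plan) {
  rate <- battery$screen$sample_rate_hz
  rows <- list()
  for (st in battery$stimuli) {
    n <- as.integer(round(st$duration_s * rate))
    p <- plan[[st$id]]
    stopifnot(sum(p$aoi) + p$out + p$invalid == n)
    x <- numeric(0); y <- numeric(0); valid <- integer(0)
    for (k in seq_along(st$aois)) {
      r <- st$aois[[k]]$rect
      cx <- (r[1] + r[3]) / 2; cy <- (r[2] + r[4]) / 2
      x <- c(x, rep(cx, p$aoi[k])); y <- c(y, rep(cy, p$aoi[k]))
      valid <- c(valid, rep(1L, p$aoi[k]))
    }
    x <- c(x, rep(1, p$out)); y <- c(y, rep(1, p$out))  # (1,1) outside AoIs
    valid <- c(valid, rep(1L, p$out))
    x <- c(x, rep(NA_real_, p$invalid)); y <- c(y, rep(NA_real_, p$invalid))
    valid <- c(valid, rep(0L, p$invalid))
    rows[[st$id]] <- data.frame(
      participant_id = pid, stimulus_id = st$id,
      t_ms = (seq_len(n) - 1) * (1000 / rate),
      x_px = x, y_px = y, valid = valid, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# Random stream on the tiny battery (for oracle recounts).
random_stream <- function(pid, battery) {
  rate <- battery$screen$sample_rate_hz
  rows <- lapply(battery$stimuli, function(st) {
    n <- as.integer(round(st$duration_s * rate))
    valid <- stats::rbinom(n, 1L, 0.85)
    x <- stats::runif(n, 0, battery$screen$width_px)
    y <- stats::runif(n, 0, battery$screen$height_px)
    x[valid == 0] <- NA; y[valid == 0] <- NA
    data.frame(participant_id = pid, stimulus_id = st$id,
               t_ms = (seq_len(n) - 1) * (1000 / rate),
               x_px = x, y_px = y, valid = valid, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Brute-force AUC over all pairs (the oracle the rank formula must match).
brute_auc <- function(asd, td, direction) {
  sa <- if (direction == "asd_lower") -asd else asd
  st <- if (direction == "asd_lower") -td else td
  wins <- 0
  for (a in sa) for (t in st) wins <- wins + (a > t) + 0.5 * (a == t)
  wins / (length(sa) * length(st))
}

# Small cohort params for fast generator tests: no low-availability cases,
# no missing covariates.
small_params <- function(n_asd = 8L, n_td = 8L) {
  p <- default_cohort_params()
  p$n_asd <- as.integer(n_asd)
  p$n_td <- as.integer(n_td)
  p$availability$asd$low_values <- numeric(0)
  p$srs$asd$n_missing <- 0L
  validate_cohort_params(p)
  p
}
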