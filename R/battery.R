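# Stimulus battery: screen constants, AoI geometry, battery config I/O.
#
# Coordinates are 0-based pixels, origin top-left, x rightward, y downward.
# Rectangles are half-open [x0, x1) x [y0, y1): a point on the right or
# bottom edge lies outside, so adjacent AoIs can never double-count a sample.

#' Screen and sampling constants
#'
#' The reference device records gaze on a 1280 x 1024 display at 50 Hz
#' (one sample every 20 ms).
#'
#' @param width_px,height_px display size in pixels.
#' @param sample_rate_hz gaze sampling rate in samples per second.
#' @return A `gf_screen` list.
#' @export
screen_spec <- function(width_px = 1280L, height_px = 1024L, sample_rate_hz = 50L) {
  width_px <- as.integer(width_px); height_px <- as.integer(height_px)
  sample_rate_hz <- as.integer(sample_rate_hz)
  if (is.na(width_px) || width_px <= 0L || is.na(height_px) || height_px <= 0L ||
      is.na(sample_rate_hz) || sample_rate_hz <= 0L)
    gf_stop("screen dimensions and sample rate must be positive integers",
            "gf_config_error")
  structure(list(width_px = width_px, height_px = height_px,
                 sample_rate_hz = sample_rate_hz), class = "gf_screen")
}

aoi_region <- function(id, role, rect, direction) {
  rect <- as.numeric(rect)
  if (length(rect) != 4L || anyNA(rect))
    gf_stop(sprintf("AoI '%s': rect must be four numbers (x0, y0, x1, y1)", id),
            "gf_config_error")
  if (rect[1] >= rect[3] || rect[2] >= rect[4])
    gf_stop(sprintf("AoI '%s': degenerate rectangle (need x0 < x1 and y0 < y1)", id),
            "gf_geometry_error")
  if (!role %in% c("aoi1", "aoi2"))
    gf_stop(sprintf("AoI '%s': role must be 'aoi1' or 'aoi2'", id), "gf_config_error")
  if (!direction %in% c("asd_lower", "asd_higher"))
    gf_stop(sprintf("AoI '%s': direction must be 'asd_lower' or 'asd_higher'", id),
            "gf_config_error")
  list(id = id, role = role, rect = rect, direction = direction)
}

stimulus_spec <- function(id, name, duration_s, aois, reference = TRUE) {
  if (!is.numeric(duration_s) || duration_s <= 0)
    gf_stop(sprintf("stimulus '%s': duration_s must be positive", id),
            "gf_config_error")
  structure(list(id = id, name = name, duration_s = duration_s,
                 aois = aois, reference = isTRUE(reference)),
            class = "gf_stimulus")
}

# Default AoI geometry. The reference device does not publish its AoI
# rectangles, so these are documented placeholders: an eyes band across the
# upper middle of the face and a mouth strip across the lower middle for the
# face movies; inset left/right half-screens for the side-by-side movies;
# a small lower-right window for the picture-in-picture movie. Geometry only
# affects the simulator and sample counting, never the statistics, and is
# fully configurable through the battery JSON.
default_geometry <- function() {
  list(
    eyes     = c(440, 280, 840, 430),
    mouth    = c(500, 600, 780, 740),
    left     = c(40, 112, 600, 912),
    right    = c(680, 112, 1240, 912),
    window   = c(832, 624, 1232, 944)
  )
}

#' The default eight-stimulus battery
#'
#' Eight short movies presented in order A-H: five human-face movies
#' (A still image 7 s, B blinking 7 s, C mouth moving 4 s, D silent 3 s,
#' E talking 7 s), one upright-vs-inverted biological-motion movie
#' (F, 20 s), and two people-vs-geometry movies (G same size 16 s,
#' H geometry in a small window 16 s). A-G carry two AoIs each; H carries
#' one. AoI-1 is the socially salient region (eyes, upright motion, people)
#' except for H, where the single AoI is the geometric window.
#'
#' @param screen a [screen_spec()].
#' @return A `gf_battery` object: list with `screen` and `stimuli`.
#' @export
default_battery <- function(screen = screen_spec()) {
  g <- default_geometry()
  st <- list(
    stimulus_spec("A", "Human face (still image)", 7, list(
      aoi_region("eyes",  "aoi1", g$eyes,  "asd_lower"),
      aoi_region("mouth", "aoi2", g$mouth, "asd_higher"))),
    stimulus_spec("B", "Human face (blinking)", 7, list(
      aoi_region("eyes",  "aoi1", g$eyes,  "asd_lower"),
      aoi_region("mouth", "aoi2", g$mouth, "asd_higher"))),
    stimulus_spec("C", "Human face (mouth moving)", 4, list(
      aoi_region("eyes",  "aoi1", g$eyes,  "asd_lower"),
      aoi_region("mouth", "aoi2", g$mouth, "asd_higher"))),
    stimulus_spec("D", "Human face (silent)", 3, list(
      aoi_region("eyes",  "aoi1", g$eyes,  "asd_lower"),
      aoi_region("mouth", "aoi2", g$mouth, "asd_higher"))),
    stimulus_spec("E", "Human face (talking)", 7, list(
      aoi_region("eyes",  "aoi1", g$eyes,  "asd_lower"),
      aoi_region("mouth", "aoi2", g$mouth, "asd_higher"))),
    stimulus_spec("F", "Biological motion", 20, list(
      aoi_region("upright",  "aoi1", g$left,  "asd_lower"),
      aoi_region("inverted", "aoi2", g$right, "asd_higher"))),
    stimulus_spec("G", "People and geometry (same size)", 16, list(
      aoi_region("people",   "aoi1", g$left,  "asd_lower"),
      aoi_region("geometry", "aoi2", g$right, "asd_higher"))),
    stimulus_spec("H", "People and geometry (small window)", 16, list(
      aoi_region("geometry", "aoi1", g$window, "asd_higher")))
  )
  battery <- structure(list(screen = screen, stimuli = st), class = "gf_battery")
  validate_battery(battery)
  battery
}

rects_overlap <- function(a, b) {
  a[1] < b[3] && b[1] < a[3] && a[2] < b[4] && b[2] < a[4]
}

#' Validate a battery object
#'
#' Enforces the geometric invariants: every AoI rectangle is non-degenerate
#' and inside the screen, and within one stimulus AoI rectangles are pairwise
#' disjoint (half-open semantics).
#'
#' @param battery a `gf_battery`.
#' @return `battery`, invisibly; errors on violation.
#' @export
validate_battery <- function(battery) {
  sc <- battery$screen
  ids <- vapply(battery$stimuli, `[[`, "", "id")
  if (anyDuplicated(ids))
    gf_stop("duplicate stimulus ids in battery", "gf_config_error")
  for (st in battery$stimuli) {
    if (length(st$aois) < 1L)
      gf_stop(sprintf("stimulus '%s' has no AoIs", st$id), "gf_config_error")
    for (a in st$aois) {
      r <- a$rect
      if (r[1] < 0 || r[2] < 0 || r[3] > sc$width_px || r[4] > sc$height_px)
        gf_stop(sprintf("stimulus '%s' AoI '%s': rectangle outside the screen",
                        st$id, a$id), "gf_geometry_error")
    }
    if (length(st$aois) > 1L) {
      for (i in seq_len(length(st$aois) - 1L)) for (j in (i + 1L):length(st$aois)) {
        if (rects_overlap(st$aois[[i]]$rect, st$aois[[j]]$rect))
          gf_stop(sprintf("stimulus '%s': AoIs '%s' and '%s' overlap",
                          st$id, st$aois[[i]]$id, st$aois[[j]]$id),
                  "gf_geometry_error")
      }
    }
    area <- sum(vapply(st$aois, function(a)
      (a$rect[3] - a$rect[1]) * (a$rect[4] - a$rect[2]), 0))
    if (area > sc$width_px * sc$height_px)
      gf_stop(sprintf("stimulus '%s': AoI area exceeds the screen", st$id),
              "gf_geometry_error")
  }
  invisible(battery)
}

#' Tabulate the battery's AoI items
#'
#' One row per (stimulus, AoI) pair in presentation order. The `item`
#' column (`"A.eyes"`, `"G.people"`, ...) is the key used by every
#' downstream stage.
#'
#' @param battery a `gf_battery`.
#' @return data.frame with columns `item`, `stimulus`, `aoi`, `role`,
#'   `direction`, `duration_s`, `n_samples`.
#' @export
battery_items <- function(battery) {
  rate <- battery$screen$sample_rate_hz
  rows <- lapply(battery$stimuli, function(st) {
    data.frame(
      item = paste0(st$id, ".", vapply(st$aois, `[[`, "", "id")),
      stimulus = st$id,
      aoi = vapply(st$aois, `[[`, "", "id"),
      role = vapply(st$aois, `[[`, "", "role"),
      direction = vapply(st$aois, `[[`, "", "direction"),
      duration_s = st$duration_s,
      n_samples = as.integer(round(st$duration_s * rate)),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

stimulus_samples <- function(battery) {
  rate <- battery$screen$sample_rate_hz
  n <- vapply(battery$stimuli, function(st) as.integer(round(st$duration_s * rate)), 0L)
  names(n) <- vapply(battery$stimuli, `[[`, "", "id")
  n
}

#' Load a battery from a JSON config
#'
#' The config mirrors the structure written by [write_battery()]:
#' `screen{width_px,height_px,sample_rate_hz}` and
#' `stimuli[{id,name,duration_s,aois[{id,role,rect,direction}]}]`.
#' Batteries are extensible: stimuli beyond the reference eight are accepted
#' and flagged with `reference = FALSE`.
#'
#' @param config path to a JSON file, or an already-parsed list.
#' @return A validated `gf_battery`.
#' @export
load_battery <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      gf_stop(sprintf("battery config not found: %s", config), "gf_config_error")
    config <- jsonlite::fromJSON(config, simplifyVector = FALSE)
  }
  if (!is.list(config) || is.null(config$screen) || is.null(config$stimuli))
    gf_stop("battery config must contain 'screen' and 'stimuli'", "gf_config_error")
  for (f in c("width_px", "height_px", "sample_rate_hz"))
    if (is.null(config$screen[[f]]))
      gf_stop(sprintf("battery config: screen is missing '%s'", f), "gf_config_error")
  sc <- screen_spec(config$screen$width_px, config$screen$height_px,
                    config$screen$sample_rate_hz)
  ref_ids <- LETTERS[1:8]
  stimuli <- lapply(config$stimuli, function(s) {
    for (f in c("id", "name", "duration_s", "aois"))
      if (is.null(s[[f]]))
        gf_stop(sprintf("battery config: a stimulus is missing '%s'", f),
                "gf_config_error")
    aois <- lapply(s$aois, function(a) {
      for (f in c("id", "role", "rect", "direction"))
        if (is.null(a[[f]]))
          gf_stop(sprintf("battery config: stimulus '%s' AoI is missing '%s'",
                          s$id, f), "gf_config_error")
      aoi_region(a$id, a$role, unlist(a$rect), a$direction)
    })
    stimulus_spec(s$id, s$name, s$duration_s, aois,
                  reference = s$id %in% ref_ids)
  })
  battery <- structure(list(screen = sc, stimuli = stimuli), class = "gf_battery")
  validate_battery(battery)
  battery
}

#' Write a battery to a JSON config file
#'
#' @param battery a `gf_battery`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_battery <- function(battery, path) {
  obj <- list(
    screen = battery$screen[c("width_px", "height_px", "sample_rate_hz")],
    stimuli = lapply(battery$stimuli, function(st) list(
      id = st$id, name = st$name, duration_s = st$duration_s,
      aois = lapply(st$aois, function(a) list(
        id = a$id, role = a$role, rect = a$rect, direction = a$direction))
    ))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
print.gf_battery <- function(x, ...) {
  cat(sprintf("<gf_battery> %d stimuli, %dx%d px @ %d Hz\n",
              length(x$stimuli), x$screen$width_px, x$screen$height_px,
              x$screen$sample_rate_hz))
  for (st in x$stimuli)
    cat(sprintf("  %s %-34s %4.0f s  [%s]\n", st$id, st$name, st$duration_s,
                paste(vapply(st$aois, `[[`, "", "id"), collapse = ", ")))
  invisible(x)
}
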