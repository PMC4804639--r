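test_that("default params encode the study conditions", {
  p <- default_cohort_params()
  expect_identical(p$n_td, 35L)
  expect_identical(p$n_asd, 26L)
  expect_equal(p$availability$asd$low_values, c(60, 58, 53, 52, 31))
  expect_length(p$availability$td$low_values, 0L)
  tg <- p$targets
  expect_equal(tg$mean_td[tg$item == "G.people"], 67.2)
  expect_equal(tg$mean_asd[tg$item == "B.eyes"], 46.7)
  expect_identical(p$srs$asd$n_missing, 4L)
  expect_equal(p$fsiq$asd$mean, 99.8)
})

test_that("same seed gives identical cohorts, different seeds differ", {
  p <- small_params()
  a <- generate_cohort(p, seed = 301)
  b <- generate_cohort(p, seed = 301)
  expect_identical(a, b)
  d <- generate_cohort(p, seed = 302)
  expect_false(identical(a$gaze, d$gaze))
  # byte-identical CSV output
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort_csv(a, d1); write_cohort_csv(b, d2)
  expect_identical(unname(tools::md5sum(file.path(d1, "gaze.csv"))),
                   unname(tools::md5sum(file.path(d2, "gaze.csv"))))
})

test_that("sample counts partition exactly for every participant x stimulus", {
  p <- small_params(4L, 4L)
  coh <- generate_cohort(p, seed = 77)
  b <- default_battery()
  nsamp <- gazeclass:::stimulus_samples(b)
  for (pid in unique(coh$gaze$participant_id)) {
    s <- coh$gaze[coh$gaze$participant_id == pid, ]
    for (st in b$stimuli) {
      chunk <- s[s$stimulus_id == st$id, ]
      expect_identical(nrow(chunk), as.integer(nsamp[[st$id]]))
      valid <- chunk$valid == 1
      in_aoi <- rep(FALSE, nrow(chunk))
      for (a in st$aois)
        in_aoi <- in_aoi | (valid & chunk$x_px >= a$rect[1] & chunk$x_px < a$rect[3] &
                              chunk$y_px >= a$rect[2] & chunk$y_px < a$rect[4])
      # valid in-AoI + valid out-of-AoI + invalid == scheduled samples
      expect_identical(sum(in_aoi) + sum(valid & !in_aoi) + sum(!valid),
                       as.integer(nsamp[[st$id]]))
      expect_true(all(diff(chunk$t_ms) == 20))
      expect_true(all(is.na(chunk$x_px[!valid])))
    }
  }
})

test_that("degenerate noise: SD-0 targets and full availability reproduce targets exactly", {
  p <- small_params(2L, 2L)
  p$targets$sd_asd[] <- 0
  p$targets$sd_td[] <- 0
  # make per-stimulus target sums feasible without rescale, set 60/20 on A
  p$targets[p$targets$item == "A.eyes", c("mean_asd", "mean_td")] <- 60
  p$targets[p$targets$item == "A.mouth", c("mean_asd", "mean_td")] <- 20
  p$availability$asd <- list(low_values = numeric(0), mean = 100, sd = 0, min = 100)
  p$availability$td <- list(low_values = numeric(0), mean = 100, sd = 0, min = 100)
  prof <- draw_attention_profile(p, "ASD", "A", availability = 100)
  expect_equal(unname(prof$aoi), c(60, 20))
  expect_equal(prof$out, 20)
  expect_equal(prof$invalid, 0)
  # conservation: AoI shares + out sum to the valid share
  profF <- draw_attention_profile(p, "TD", "F", availability = 100)
  expect_equal(sum(profF$aoi) + profF$out + profF$invalid, 100)
  # through the sample-level path percentages are multinomial around the
  # degenerate profile; availability is exact
  sim <- simulate_cohort_fixations(p, seed = 9)
  inc <- sim$fixation$included
  expect_equal(unique(inc$availability), 100)
  expect_true(all(abs(inc$A.eyes - 60) < 10))
  expect_true(all(abs(inc$A.mouth - 20) < 10))
  expect_equal(inc$A.eyes + inc$A.mouth + inc$A.out, rep(100, nrow(inc)))
})

test_that("low-availability cases surface with the configured availabilities", {
  coh <- generate_cohort(default_cohort_params(), seed = 11)
  fix <- compute_fixation_table(coh$gaze, default_battery())
  expect_identical(nrow(fix$excluded), 5L)
  merged <- merge(fix$excluded, coh$participants, by = "participant_id")
  expect_true(all(merged$group == "ASD"))
  # realized availabilities are binomial around the configured 60/58/53/52/31
  expect_true(all(abs(sort(fix$excluded$availability) -
                        sort(c(60, 58, 53, 52, 31))) < 2.5))
  expect_identical(nrow(fix$included), 56L)
})

test_that("participant metadata respects ranges and missingness", {
  coh <- generate_cohort(default_cohort_params(), seed = 21)
  pp <- coh$participants
  expect_identical(sum(is.na(pp$srs_total[pp$group == "ASD"])), 4L)
  expect_identical(sum(is.na(pp$srs_total[pp$group == "TD"])), 0L)
  expect_true(all(pp$srs_total >= 0 & pp$srs_total <= 195, na.rm = TRUE))
  expect_true(all(is.na(pp$fsiq[pp$group == "TD"])))
  expect_true(all(!is.na(pp$fsiq[pp$group == "ASD"])))
  expect_true(all(pp$age_years[pp$group == "ASD"] >= 15 &
                    pp$age_years[pp$group == "ASD"] <= 41))
  # the SRS-missing participants are retained ones, so analysed SRS n is 17
  fix <- compute_fixation_table(coh$gaze, default_battery())
  inc <- merge(fix$included, pp, by = "participant_id")
  expect_identical(sum(!is.na(inc$srs_total[inc$group == "ASD"])), 17L)
})

test_that("attention-profile draws recover a calibrated target mean", {
  p <- default_cohort_params()
  calib <- calibrate_attention_model(p)
  set.seed(404)
  draws <- replicate(2000, draw_attention_profile(
    p, "ASD", "B", availability = 95.3, calib = calib)$aoi[["B.eyes"]])
  expect_lt(abs(mean(draws) - 46.7), 1.5)
})

test_that("streaming simulation equals the two-step route exactly", {
  p <- small_params(3L, 3L)
  coh <- generate_cohort(p, seed = 55)
  two_step <- compute_fixation_table(coh$gaze, default_battery())
  stream <- simulate_cohort_fixations(p, seed = 55)
  expect_equal(stream$fixation$included, two_step$included)
  expect_identical(stream$participants, coh$participants)
})

test_that("impossible geometry with out-of-AoI mass raises a generation error", {
  b <- tiny_battery()
  # one stimulus whose single AoI covers the whole screen
  b$stimuli <- list(gazeclass:::stimulus_spec("A", "full", 1, list(
    gazeclass:::aoi_region("all", "aoi1", c(0, 0, 100, 100), "asd_lower"))))
  p <- small_params(2L, 2L)
  p$targets <- data.frame(item = "A.all", mean_asd = 50, sd_asd = 0,
                          mean_td = 50, sd_td = 0)
  p$availability$asd <- list(low_values = numeric(0), mean = 100, sd = 0, min = 100)
  p$availability$td <- p$availability$asd
  expect_error(generate_cohort(p, seed = 1, battery = b),
               class = "gf_generation_error")
})
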