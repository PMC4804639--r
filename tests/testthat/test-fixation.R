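test_that("availability is the valid share of all scheduled samples", {
  b <- tiny_battery()  # 50 + 20 = 70 scheduled samples at 10 Hz
  all_valid <- make_stream("p1", b, list(
    A = list(aoi = c(30, 10), out = 10, invalid = 0),
    B = list(aoi = 5, out = 15, invalid = 0)))
  expect_equal(compute_availability(all_valid, b), 100)

  # 70 scheduled, 14 invalid -> 80%
  s80 <- make_stream("p2", b, list(
    A = list(aoi = c(30, 10), out = 0, invalid = 10),
    B = list(aoi = 5, out = 11, invalid = 4)))
  expect_equal(compute_availability(s80, b), 80)

  # missing stimulus
  expect_error(compute_availability(all_valid[all_valid$stimulus_id == "A", ], b),
               class = "gf_stream_error")
  # wrong sample count
  expect_error(compute_availability(all_valid[-1, ], b),
               class = "gf_stream_error")
})

test_that("fixation percentages use the full stimulus duration as denominator", {
  b <- tiny_battery(rate = 50L)  # A: 250 samples, B: 100 samples
  # 227 of 350 total... here: A has 250 samples; put 100 in eyes, 50 invalid
  s <- make_stream("p1", b, list(
    A = list(aoi = c(100, 25), out = 75, invalid = 50),
    B = list(aoi = 40, out = 10, invalid = 50)))
  rec <- compute_fixation_record(s, b)
  expect_equal(rec$A.eyes, 100 / 250 * 100)
  expect_equal(rec$A.mouth, 10)
  expect_equal(rec$A.out, 30)
  expect_equal(rec$B.geometry, 40)
  # invalid share is the complement of the per-stimulus partition
  expect_equal(rec$A.eyes + rec$A.mouth + rec$A.out, 80)
  expect_equal(rec$availability, 100 * (250 - 50 + 100 - 50) / 350)
})

test_that("the printed worked example arithmetic holds: 227 in-AoI of 350", {
  # a 7 s stimulus at 50 Hz has 350 scheduled samples; 227 eye-region
  # samples give 64.857 ~ 64.9%
  b <- structure(list(
    screen = screen_spec(100L, 100L, 50L),
    stimuli = list(gazeclass:::stimulus_spec("A", "face", 7, list(
      gazeclass:::aoi_region("eyes", "aoi1", c(10, 10, 50, 40), "asd_lower"))))),
    class = "gf_battery")
  s <- make_stream("p1", b, list(A = list(aoi = 227, out = 53, invalid = 70)))
  rec <- compute_fixation_record(s, b)
  expect_equal(rec$A.eyes, 100 * 227 / 350)
  expect_equal(round(rec$A.eyes, 1), 64.9)
  expect_equal(rec$availability, 80)
})

test_that("availability exclusion is strict and partitions the roster", {
  b <- tiny_battery(rate = 10L)  # 70 samples total
  # availability exactly 80 must be retained (< is strict)
  plans <- list(
    keep = list(A = list(aoi = c(30, 10), out = 4, invalid = 6),
                B = list(aoi = 5, out = 7, invalid = 8)),   # 80%
    drop = list(A = list(aoi = c(20, 10), out = 5, invalid = 15),
                B = list(aoi = 5, out = 9, invalid = 6)))   # 70%
  gaze <- rbind(make_stream("keep", b, plans$keep),
                make_stream("drop", b, plans$drop))
  fix <- compute_fixation_table(gaze, b)
  expect_identical(fix$included$participant_id, "keep")
  expect_identical(fix$excluded$participant_id, "drop")
  expect_equal(fix$excluded$availability, 70)
})

test_that("all-invalid streams yield zero percentages and are excluded", {
  b <- tiny_battery()
  s <- make_stream("dead", b, list(
    A = list(aoi = c(0, 0), out = 0, invalid = 50),
    B = list(aoi = 0, out = 0, invalid = 20)))
  fix <- compute_fixation_table(s, b)
  expect_identical(nrow(fix$included), 0L)
  expect_equal(fix$excluded$availability, 0)
  rec <- compute_fixation_record(s, b)
  expect_equal(rec$A.eyes, 0)
  expect_equal(rec$B.geometry, 0)
})

test_that("streaming computation equals a brute-force recount on random streams", {
  b <- tiny_battery()
  set.seed(88)
  for (rep in 1:8) {
    s <- random_stream(sprintf("r%d", rep), b)
    rec <- compute_fixation_record(s, b)
    for (st in b$stimuli) {
      chunk <- s[s$stimulus_id == st$id, ]
      for (a in st$aois) {
        n_in <- 0L
        for (i in seq_len(nrow(chunk))) {  # deliberate per-sample recount
          if (chunk$valid[i] == 1 &&
              chunk$x_px[i] >= a$rect[1] && chunk$x_px[i] < a$rect[3] &&
              chunk$y_px[i] >= a$rect[2] && chunk$y_px[i] < a$rect[4])
            n_in <- n_in + 1L
        }
        expect_equal(rec[[paste0(st$id, ".", a$id)]],
                     100 * n_in / nrow(chunk))
      }
    }
  }
})

test_that("invalidating samples never increases any AoI percentage", {
  b <- tiny_battery()
  set.seed(12)
  s <- random_stream("m", b)
  rec0 <- compute_fixation_record(s, b)
  s2 <- s
  flip <- which(s2$valid == 1)[c(TRUE, FALSE)]  # invalidate every other valid
  s2$valid[flip] <- 0L
  s2$x_px[flip] <- NA; s2$y_px[flip] <- NA
  rec1 <- compute_fixation_record(s2, b)
  items <- battery_items(b)$item
  expect_true(all(unlist(rec1[items]) <= unlist(rec0[items])))
  expect_lt(rec1$availability, rec0$availability)
})
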