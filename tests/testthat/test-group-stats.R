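fx <- load_fixtures()

test_that("two-sample t from summaries matches printed values", {
  # identical summaries: perfect symmetry
  r <- two_sample_t(50, 10, 20, 50, 10, 20, "pooled")
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)

  # blinking eyes row reproduces under Welch
  rw <- two_sample_t(46.7, 31.6, 21, 77.4, 24.1, 35, "welch")
  expect_equal(abs(rw$t), 3.83, tolerance = 0.01)

  # still-image eyes row reproduces under pooled (printed 2.83)
  rp <- two_sample_t(64.9, 22.9, 21, 80.9, 19.0, 35, "pooled")
  expect_equal(abs(rp$t), 2.83, tolerance = 0.05)
  expect_equal(rp$df, 54)

  # swapping groups flips t, keeps p
  r1 <- two_sample_t(60, 10, 12, 50, 12, 15, "welch")
  r2 <- two_sample_t(50, 12, 15, 60, 10, 12, "welch")
  expect_equal(r1$t, -r2$t)
  expect_equal(r1$p, r2$p)

  expect_error(two_sample_t(5, 0, 10, 5, 0, 10), class = "gf_undefined_statistic")
  expect_error(two_sample_t(5, 1, 1, 5, 1, 10), class = "gf_insufficient_data")
})

test_that("pooled t and Cohen's d satisfy t = d / sqrt(1/n1 + 1/n2)", {
  set.seed(31)
  for (i in 1:20) {
    n1 <- sample(3:30, 1); n2 <- sample(3:30, 1)
    m1 <- runif(1, 0, 100); m2 <- runif(1, 0, 100)
    s1 <- runif(1, 1, 30); s2 <- runif(1, 1, 30)
    t <- two_sample_t(m1, s1, n1, m2, s2, n2, "pooled")$t
    d <- cohens_d(m1, s1, n1, m2, s2, n2)
    expect_equal(abs(t), d / sqrt(1 / n1 + 1 / n2))
  }
})

test_that("Cohen's d reproduces the printed effect sizes from summaries", {
  expect_equal(cohens_d(50, 5, 10, 50, 7, 12), 0)
  expect_equal(cohens_d(22.1, 19.2, 21, 7.0, 15.7, 35), 0.89, tolerance = 0.03)
  expect_equal(cohens_d(47.6, 23.1, 21, 67.2, 16.6, 35), 1.03, tolerance = 0.03)
  expect_error(cohens_d(5, 0, 10, 5, 0, 10), class = "gf_undefined_statistic")
})

test_that("Bonferroni level is 0.05 over the stimulus AoI count", {
  b <- default_battery()
  expect_equal(bonferroni_alpha(b$stimuli[[1]]), 0.025)  # two AoIs
  expect_equal(bonferroni_alpha(b$stimuli[[8]]), 0.05)   # single AoI
  expect_equal(bonferroni_alpha(4), 0.0125)
})

test_that("summary-level comparison reproduces the printed significance pattern", {
  cmp <- compare_from_summary(fx$table2, n_asd = 21, n_td = 35, variant = "auto")
  sig <- cmp$item[cmp$significant & cmp$item != "availability"]
  expect_setequal(sig, c("A.eyes", "B.eyes", "B.mouth", "D.eyes", "D.mouth",
                         "G.people", "G.geometry", "H.geometry"))
  # eyes rows significant for A/B/D but not C/E; F rows not significant
  expect_false(any(c("C.eyes", "C.mouth", "E.eyes", "E.mouth",
                     "F.upright", "F.inverted") %in% sig))
  expect_false(cmp$significant[cmp$item == "availability"])
  # availability is judged at 0.05 outside the Bonferroni families
  expect_equal(cmp$alpha[cmp$item == "availability"], 0.05)
  expect_equal(cmp$alpha[cmp$item == "H.geometry"], 0.05)
  expect_equal(cmp$alpha[cmp$item == "B.eyes"], 0.025)
})

test_that("every printed t is recovered by pooled or Welch within 0.1", {
  cmp <- compare_from_summary(fx$table2, n_asd = 21, n_td = 35, variant = "auto")
  for (i in seq_len(nrow(cmp))) {
    printed <- fx$table2$t_value[fx$table2$item == cmp$item[i]]
    best <- min(abs(abs(cmp$t_pooled[i]) - printed),
                abs(abs(cmp$t_welch[i]) - printed))
    expect_lt(best, 0.1)
  }
})

test_that("group comparison on raw data flags identical groups as null", {
  b <- tiny_battery()
  set.seed(5)
  vals <- runif(12, 20, 60)
  rec <- data.frame(participant_id = sprintf("p%02d", 1:12),
                    availability = rep(100 - runif(6, 0, 6), 2),
                    A.eyes = vals, A.mouth = rev(vals), A.out = 0,
                    B.geometry = vals, B.out = 0, check.names = FALSE)
  participants <- data.frame(participant_id = rec$participant_id,
                             group = rep(c("ASD", "TD"), each = 6))
  # same values in both groups: no significant rows
  rec2 <- rec; rec2$A.eyes <- rep(vals[1:6], 2); rec2$A.mouth <- rep(vals[7:12], 2)
  rec2$B.geometry <- rep(vals[1:6], 2)
  fix2 <- gazeclass:::fixation_table_from_records(rec2, b)
  cmp <- compare_groups(fix2, participants, b)
  expect_false(any(cmp$significant))
  expect_true(all(cmp$d[cmp$item != "availability"] < 1e-8))
})

test_that("variant policies select pooled vs Welch as instructed", {
  b <- tiny_battery()
  set.seed(6)
  n <- 40
  rec <- data.frame(participant_id = sprintf("p%02d", 1:n),
                    availability = 100 - runif(n, 0, 8),
                    A.eyes = c(rnorm(n / 2, 40, 2), rnorm(n / 2, 55, 25)),
                    A.mouth = rnorm(n, 20, 5), A.out = 0,
                    B.geometry = rnorm(n, 30, 5), B.out = 0, check.names = FALSE)
  fix <- gazeclass:::fixation_table_from_records(rec, b)
  participants <- data.frame(participant_id = rec$participant_id,
                             group = rep(c("ASD", "TD"), each = n / 2))
  lev <- compare_groups(fix, participants, b, variant_policy = "levene")
  # grossly unequal variances on A.eyes: Levene policy must go Welch there
  expect_identical(lev$variant[lev$item == "A.eyes"], "welch")
  pool <- compare_groups(fix, participants, b, variant_policy = "pooled")
  expect_true(all(pool$variant == "pooled"))
  wel <- compare_groups(fix, participants, b, variant_policy = "welch")
  expect_true(all(wel$variant == "welch"))
})

test_that("insufficient groups after exclusion raise an error", {
  b <- tiny_battery()
  rec <- data.frame(participant_id = c("a1", "t1", "t2"), availability = 100,
                    A.eyes = c(10, 20, 30), A.mouth = c(1, 2, 3), A.out = 0,
                    B.geometry = c(5, 6, 7), B.out = 0, check.names = FALSE)
  fix <- gazeclass:::fixation_table_from_records(rec, b)
  participants <- data.frame(participant_id = rec$participant_id,
                             group = c("ASD", "TD", "TD"))
  expect_error(compare_groups(fix, participants, b),
               class = "gf_insufficient_data")
})

test_that("correlations match the closed-form oracle and handle edge cases", {
  # closed-form on the 5-point toy: Sxy = 8, Sxx = Syy = 10 -> r = 0.8
  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 5)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  r_hand <- sxy / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(r_hand, 0.8)
  expect_equal(stats::cor(x, y), r_hand)

  # streaming (cor) equals the closed-form on random vectors
  set.seed(14)
  for (i in 1:25) {
    n <- sample(3:20, 1)
    a <- runif(n); b <- runif(n)
    rc <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    expect_equal(stats::cor(a, b), rc, tolerance = 1e-12)
  }
})

test_that("within-group correlations cover SRS both groups and FSIQ in ASD", {
  b <- tiny_battery()
  set.seed(7)
  n <- 16
  rec <- data.frame(participant_id = sprintf("p%02d", 1:n), availability = 100,
                    A.eyes = runif(n, 10, 90), A.mouth = runif(n, 0, 30),
                    A.out = 0, B.geometry = runif(n, 0, 60), B.out = 0,
                    check.names = FALSE)
  fix <- gazeclass:::fixation_table_from_records(rec, b)
  participants <- data.frame(
    participant_id = rec$participant_id,
    group = rep(c("ASD", "TD"), each = n / 2),
    srs_total = c(round(runif(n / 2, 80, 150)), round(runif(n / 2, 20, 90))),
    fsiq = c(round(runif(n / 2, 85, 120)), rep(NA, n / 2)))
  res <- within_group_correlations(fix, participants)
  expect_setequal(unique(res$covariate), c("SRS", "FSIQ"))
  expect_identical(unique(res$group[res$covariate == "FSIQ"]), "ASD")
  expect_equal(nrow(res), length(fix$items) * 3)
  expect_true(all(res$r >= -1 & res$r <= 1))
  expect_true(all(res$n >= 3))

  # perfectly linear toy gives r = 1
  p2 <- participants
  p2$srs_total <- seq_len(n)
  f2 <- fix; f2$included$A.eyes <- seq_len(n) * 2 + 3
  res2 <- within_group_correlations(f2, p2)
  expect_equal(res2$r[res2$item == "A.eyes" & res2$covariate == "SRS"], c(1, 1))

  # constant covariate: undefined correlation
  p3 <- participants
  p3$srs_total <- 100
  expect_error(within_group_correlations(fix, p3),
               class = "gf_undefined_statistic")
})
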