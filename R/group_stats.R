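# Group-difference stage: independent t tests (pooled or Welch, with a
# Levene-based per-item choice as the default policy), Cohen's d from the
# df-weighted pooled SD, per-stimulus Bonferroni significance levels, and
# within-group correlations against SRS and FSIQ.

#' Two-sample t test from summary statistics
#'
#' @param mean1,sd1,n1 first group's mean, SD and size.
#' @param mean2,sd2,n2 second group's mean, SD and size.
#' @param variant `"pooled"` (equal-variance, df = n1 + n2 - 2) or
#'   `"welch"` (Welch-Satterthwaite df).
#' @return list with `t` (sign of `mean1 - mean2`), `df`, `p` (two-sided).
#' @export
two_sample_t <- function(mean1, sd1, n1, mean2, sd2, n2,
                         variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (n1 < 2 || n2 < 2)
    gf_stop("need at least two observations per group", "gf_insufficient_data")
  if (sd1 < 0 || sd2 < 0) gf_stop("SDs must be non-negative", "gf_config_error")
  if (sd1 == 0 && sd2 == 0 && mean1 == mean2)
    gf_stop("both SDs are zero and the means are equal: t is undefined",
            "gf_undefined_statistic")
  if (variant == "pooled") {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  t <- if (se == 0) sign(mean1 - mean2) * Inf else (mean1 - mean2) / se
  p <- if (is.infinite(t)) 0 else 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

#' Cohen's d (pooled-SD standardized absolute difference)
#'
#' Always uses the df-weighted pooled SD regardless of which t variant is
#' reported, following the convention d > 0.5 medium, d > 0.8 large.
#'
#' @inheritParams two_sample_t
#' @return non-negative effect size.
#' @export
cohens_d <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2)
    gf_stop("need at least two observations per group", "gf_insufficient_data")
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  if (sp == 0)
    gf_stop("pooled SD is zero: d is undefined", "gf_undefined_statistic")
  abs(mean1 - mean2) / sp
}

#' Per-stimulus Bonferroni significance level
#'
#' `0.05 / number of AoIs`: 0.025 for the two-AoI stimuli, 0.05 for the
#' single-AoI stimulus.
#'
#' @param stimulus a `gf_stimulus`, or directly the number of AoIs.
#' @return the significance level.
#' @export
bonferroni_alpha <- function(stimulus) {
  n <- if (is.numeric(stimulus)) stimulus else length(stimulus$aois)
  if (n < 1) gf_stop("stimulus must have at least one AoI", "gf_config_error")
  0.05 / n
}

effect_flag <- function(d, medium = 0.5, large = 0.8) {
  ifelse(d > large, "large", ifelse(d > medium, "medium", "none"))
}

# Levene test (center = mean), the classical equal-variance screen.
levene_equal_var <- function(x, y, alpha = 0.05) {
  values <- c(x, y)
  g <- factor(rep(c("1", "2"), c(length(x), length(y))))
  p <- car::leveneTest(values, g, center = mean)[["Pr(>F)"]][1]
  is.na(p) || p >= alpha
}

compare_one <- function(x, y, n1 = length(x), n2 = length(y),
                        variant_policy = "levene",
                        summaries = NULL, printed_t = NA_real_) {
  if (is.null(summaries)) {
    s <- list(mean1 = mean(x), sd1 = stats::sd(x), n1 = n1,
              mean2 = mean(y), sd2 = stats::sd(y), n2 = n2)
  } else s <- summaries
  variant <- switch(variant_policy,
    pooled = "pooled",
    welch = "welch",
    levene = if (levene_equal_var(x, y)) "pooled" else "welch",
    auto = {
      # summary-level: keep the variant that best matches a printed t
      tp <- two_sample_t(s$mean1, s$sd1, s$n1, s$mean2, s$sd2, s$n2, "pooled")
      tw <- two_sample_t(s$mean1, s$sd1, s$n1, s$mean2, s$sd2, s$n2, "welch")
      if (!is.na(printed_t) &&
          abs(abs(tw$t) - printed_t) < abs(abs(tp$t) - printed_t)) "welch"
      else "pooled"
    },
    gf_stop(sprintf("unknown variant policy '%s'", variant_policy),
            "gf_config_error"))
  tt <- two_sample_t(s$mean1, s$sd1, s$n1, s$mean2, s$sd2, s$n2, variant)
  d <- cohens_d(s$mean1, s$sd1, s$n1, s$mean2, s$sd2, s$n2)
  c(s, list(t = tt$t, df = tt$df, p = tt$p, variant = variant, d = d))
}

#' Group comparison of every AoI item (plus availability)
#'
#' One independent t test per (stimulus, AoI) item comparing ASD against
#' TD among included participants, preceded by the availability comparison.
#' Significance is judged against the per-stimulus Bonferroni level
#' (`0.05 / number of AoIs`); the availability row is a preliminary test
#' outside the Bonferroni families and is judged at 0.05.
#'
#' @param fixation a `gf_fixation_table`.
#' @param participants participant metadata with `participant_id`, `group`.
#' @param battery a `gf_battery`.
#' @param variant_policy `"levene"` (default: centre-mean Levene test at
#'   0.05 picks pooled vs Welch per item), `"pooled"`, or `"welch"`.
#' @return data.frame, one row per item: group summaries, `t`, `df`, `p`,
#'   `variant`, `d`, `alpha`, `effect_flag`, `significant`, `role`,
#'   `direction`.
#' @export
compare_groups <- function(fixation, participants, battery,
                           variant_policy = c("levene", "pooled", "welch")) {
  variant_policy <- match.arg(variant_policy)
  inc <- merge(fixation$included,
               participants[c("participant_id", "group")],
               by = "participant_id", sort = FALSE)
  x_asd <- inc[inc$group == "ASD", , drop = FALSE]
  x_td <- inc[inc$group == "TD", , drop = FALSE]
  if (nrow(x_asd) < 2L || nrow(x_td) < 2L)
    gf_stop("fewer than two participants in a group after exclusion",
            "gf_insufficient_data")
  items <- battery_items(battery)
  alpha_by_stim <- vapply(battery$stimuli, bonferroni_alpha, 0)
  names(alpha_by_stim) <- vapply(battery$stimuli, `[[`, "", "id")

  one_row <- function(col, item, role, direction, alpha) {
    r <- compare_one(x_asd[[col]], x_td[[col]], variant_policy = variant_policy)
    data.frame(
      item = item, n_asd = r$n1, mean_asd = r$mean1, sd_asd = r$sd1,
      n_td = r$n2, mean_td = r$mean2, sd_td = r$sd2,
      t = r$t, df = r$df, p = r$p, variant = r$variant, d = r$d,
      alpha = alpha, effect_flag = effect_flag(r$d),
      significant = r$p < alpha, role = role, direction = direction,
      stringsAsFactors = FALSE)
  }
  out <- list(one_row("availability", "availability", NA_character_,
                      NA_character_, 0.05))
  for (i in seq_len(nrow(items))) {
    out[[length(out) + 1L]] <- one_row(
      items$item[i], items$item[i], items$role[i], items$direction[i],
      alpha_by_stim[[items$stimulus[i]]])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Group comparison from printed summary statistics
#'
#' Summary-level variant of [compare_groups()] for reference tables that
#' print only group means and SDs: recomputes t, p and pooled-SD Cohen's d
#' per item. With `variant = "auto"` and a printed t column present, the
#' variant (pooled vs Welch) that reproduces the printed t more closely is
#' kept per row; otherwise the requested variant is used throughout.
#'
#' @param summaries data.frame with columns `item`, `mean_asd`, `sd_asd`,
#'   `mean_td`, `sd_td`, optionally `t_value` (printed).
#' @param n_asd,n_td group sizes behind the summaries.
#' @param battery a `gf_battery`.
#' @param variant `"auto"`, `"pooled"` or `"welch"`.
#' @return data.frame like [compare_groups()] (with both recomputed
#'   variants' t values alongside).
#' @export
compare_from_summary <- function(summaries, n_asd = 21L, n_td = 35L,
                                 battery = default_battery(),
                                 variant = c("auto", "pooled", "welch")) {
  variant <- match.arg(variant)
  items <- battery_items(battery)
  alpha_by_stim <- vapply(battery$stimuli, bonferroni_alpha, 0)
  names(alpha_by_stim) <- vapply(battery$stimuli, `[[`, "", "id")
  rows <- lapply(seq_len(nrow(summaries)), function(i) {
    srow <- summaries[i, ]
    s <- list(mean1 = srow$mean_asd, sd1 = srow$sd_asd, n1 = n_asd,
              mean2 = srow$mean_td, sd2 = srow$sd_td, n2 = n_td)
    printed_t <- if ("t_value" %in% names(srow)) srow$t_value else NA_real_
    r <- compare_one(NULL, NULL, variant_policy = variant,
                     summaries = s, printed_t = printed_t)
    tp <- two_sample_t(s$mean1, s$sd1, s$n1, s$mean2, s$sd2, s$n2, "pooled")
    tw <- two_sample_t(s$mean1, s$sd1, s$n1, s$mean2, s$sd2, s$n2, "welch")
    is_avail <- srow$item == "availability"
    idx <- match(srow$item, items$item)
    alpha <- if (is_avail) 0.05 else alpha_by_stim[[items$stimulus[idx]]]
    data.frame(
      item = srow$item, n_asd = n_asd, mean_asd = s$mean1, sd_asd = s$sd1,
      n_td = n_td, mean_td = s$mean2, sd_td = s$sd2,
      t = r$t, df = r$df, p = r$p, variant = r$variant,
      t_pooled = tp$t, t_welch = tw$t, d = r$d,
      alpha = alpha, effect_flag = effect_flag(r$d),
      significant = r$p < alpha,
      role = if (is_avail) NA_character_ else items$role[idx],
      direction = if (is_avail) NA_character_ else items$direction[idx],
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Within-group correlations with psychometric scores
#'
#' Pearson product-moment correlations between each item's fixation
#' percentage and the SRS total (within ASD and TD separately) and the
#' FSIQ (ASD only), with pairwise deletion of missing covariates.
#' p values are uncorrected two-sided tests at 0.05.
#'
#' @param fixation a `gf_fixation_table`.
#' @param participants metadata with `participant_id`, `group`,
#'   `srs_total`, `fsiq`.
#' @return data.frame: `item`, `covariate`, `group`, `n`, `r`, `p`,
#'   `significant`.
#' @export
within_group_correlations <- function(fixation, participants) {
  inc <- merge(fixation$included, participants, by = "participant_id",
               sort = FALSE)
  combos <- list(list(cov = "srs_total", label = "SRS", group = "ASD"),
                 list(cov = "srs_total", label = "SRS", group = "TD"),
                 list(cov = "fsiq", label = "FSIQ", group = "ASD"))
  rows <- list()
  for (item in fixation$items) {
    for (cb in combos) {
      sub <- inc[inc$group == cb$group, c(item, cb$cov)]
      sub <- sub[stats::complete.cases(sub), ]
      if (nrow(sub) < 3L)
        gf_stop(sprintf("fewer than 3 complete pairs for %s/%s in %s",
                        item, cb$label, cb$group), "gf_insufficient_data")
      if (stats::sd(sub[[cb$cov]]) == 0 || stats::sd(sub[[item]]) == 0)
        gf_stop(sprintf("zero variance for %s/%s in %s: r undefined",
                        item, cb$label, cb$group), "gf_undefined_statistic")
      ct <- stats::cor.test(sub[[item]], sub[[cb$cov]], method = "pearson")
      rows[[length(rows) + 1L]] <- data.frame(
        item = item, covariate = cb$label, group = cb$group,
        n = nrow(sub), r = unname(ct$estimate), p = ct$p.value,
        significant = ct$p.value < 0.05, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
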