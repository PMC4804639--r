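# Rank-based ROC analysis with direction-aware Youden cutoffs.
#
# Every item has a known ASD-typical direction (eyes/people: ASD lower;
# mouth/inverted/geometry: ASD higher). Scores are oriented so that the
# ASD-typical direction is positive before AUC and cutoff computation, and
# cutoff rules keep strict inequalities exactly as printed ("<81", ">31"):
# a value equal to the cutoff never meets the rule.

orient <- function(x, direction) {
  if (direction == "asd_lower") -x else x
}

#' Area under the ROC curve (rank statistic)
#'
#' `P(oriented ASD score > oriented TD score) + 1/2 P(tie)` - the
#' Mann-Whitney statistic normalised by `n1 * n2`, computed from midranks.
#'
#' @param values_asd,values_td fixation percentages per group.
#' @param direction `"asd_lower"` or `"asd_higher"`: the ASD-typical side.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(values_asd, values_td,
                    direction = c("asd_lower", "asd_higher")) {
  direction <- match.arg(direction)
  if (!length(values_asd) || !length(values_td))
    gf_stop("both groups must be nonempty", "gf_insufficient_data")
  sa <- orient(values_asd, direction)
  st <- orient(values_td, direction)
  n1 <- length(sa); n2 <- length(st)
  r <- rank(c(sa, st))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Hanley-McNeil confidence interval for an AUC
#'
#' Normal-approximation interval from the exponential-model variance of
#' Hanley & McNeil (1982), clamped to \[0, 1\].
#'
#' @param auc the area estimate.
#' @param n1,n2 group sizes.
#' @param conf confidence level.
#' @return list with `ci_low`, `ci_high`, `se`.
#' @export
auc_ci_hanley <- function(auc, n1, n2, conf = 0.95) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  v <- (auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) + (n2 - 1) * (q2 - auc^2)) /
    (n1 * n2)
  se <- sqrt(max(v, 0))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  list(ci_low = max(0, auc - z * se), ci_high = min(1, auc + z * se), se = se)
}

rule_sens_spec <- function(cut, values_asd, values_td, direction) {
  if (direction == "asd_lower") {
    sens <- mean(values_asd < cut); spec <- mean(values_td >= cut)
  } else {
    sens <- mean(values_asd > cut); spec <- mean(values_td <= cut)
  }
  c(sens = sens, spec = spec)
}

#' Youden-optimal directional cutoff
#'
#' Sweeps candidate thresholds (midpoints between adjacent distinct pooled
#' values, plus one candidate beyond each extreme) and returns the one
#' maximising Youden's J = sensitivity + specificity - 1 under the strict
#' inequality rule. Ties are broken toward higher specificity, then toward
#' the more conservative (more extreme) threshold. The reported cutoff is
#' additionally rounded to integer percent, as such cutoffs are printed.
#'
#' @inheritParams roc_auc
#' @param item optional item label carried into the rule.
#' @return A `gf_cutoff_rule`: `item`, `direction`, `cutoff` (raw),
#'   `cutoff_report` (integer), `sens_at_cutoff`, `spec_at_cutoff`,
#'   `youden_j`.
#' @export
select_cutoff <- function(values_asd, values_td,
                          direction = c("asd_lower", "asd_higher"),
                          item = NA_character_) {
  direction <- match.arg(direction)
  if (!length(values_asd) || !length(values_td))
    gf_stop("both groups must be nonempty", "gf_insufficient_data")
  v <- sort(unique(c(values_asd, values_td)))
  cand <- c(v[1] - 1, if (length(v) > 1) (v[-1] + v[-length(v)]) / 2,
            v[length(v)] + 1)
  ss <- t(vapply(cand, rule_sens_spec, c(sens = 0, spec = 0),
                 values_asd = values_asd, values_td = values_td,
                 direction = direction))
  j <- ss[, "sens"] + ss[, "spec"] - 1
  extreme <- if (direction == "asd_lower") -cand else cand
  ord <- order(-j, -ss[, "spec"], extreme)
  best <- ord[1]
  structure(list(
    item = item, direction = direction, cutoff = cand[best],
    cutoff_report = round_half_up(cand[best], 0),
    sens_at_cutoff = unname(ss[best, "sens"]),
    spec_at_cutoff = unname(ss[best, "spec"]),
    youden_j = j[best]
  ), class = "gf_cutoff_rule")
}

#' Build cutoff rules from a printed ROC table
#'
#' Turns reference rows (`item`, `direction`, integer `cutoff`) into
#' `gf_cutoff_rule`s so the published classifier can be applied verbatim,
#' independent of re-derived cutoffs.
#'
#' @param roc_table data.frame like `load_fixtures()$table4`.
#' @param items optional subset of items, kept in the given order.
#' @return list of `gf_cutoff_rule`.
#' @export
cutoff_rules_from_table <- function(roc_table, items = roc_table$item) {
  rows <- roc_table[match(items, roc_table$item), ]
  if (anyNA(rows$item))
    gf_stop("requested items missing from the ROC table", "gf_config_error")
  lapply(seq_len(nrow(rows)), function(i) structure(list(
    item = rows$item[i], direction = rows$direction[i],
    cutoff = rows$cutoff[i], cutoff_report = rows$cutoff[i],
    sens_at_cutoff = NA_real_, spec_at_cutoff = NA_real_,
    youden_j = NA_real_), class = "gf_cutoff_rule"))
}

#' Per-item ROC analysis
#'
#' AUC (oriented to the ASD-typical direction), Hanley-McNeil 95% CI and
#' Youden cutoff for every AoI item.
#'
#' @param fixation a `gf_fixation_table`.
#' @param participants metadata with `participant_id`, `group`.
#' @param battery a `gf_battery`.
#' @return data.frame: `item`, `direction`, `auc`, `ci_low`, `ci_high`,
#'   `cutoff`, `cutoff_report`, `sens_at_cutoff`, `spec_at_cutoff`.
#' @export
roc_analysis <- function(fixation, participants, battery) {
  inc <- merge(fixation$included, participants[c("participant_id", "group")],
               by = "participant_id", sort = FALSE)
  items <- battery_items(battery)
  rows <- lapply(seq_len(nrow(items)), function(i) {
    it <- items$item[i]; dir <- items$direction[i]
    va <- inc[[it]][inc$group == "ASD"]; vt <- inc[[it]][inc$group == "TD"]
    a <- roc_auc(va, vt, dir)
    ci <- auc_ci_hanley(a, length(va), length(vt))
    rule <- select_cutoff(va, vt, dir, item = it)
    data.frame(item = it, direction = dir, auc = a,
               ci_low = ci$ci_low, ci_high = ci$ci_high,
               cutoff = rule$cutoff, cutoff_report = rule$cutoff_report,
               sens_at_cutoff = rule$sens_at_cutoff,
               spec_at_cutoff = rule$spec_at_cutoff,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Select the discriminant item panel
#'
#' AoI-1 items whose Cohen's d exceeds `d_min`, in battery order: the
#' effect-size screen that narrows the battery to its well-separating
#' socially salient regions.
#'
#' @param comparisons output of [compare_groups()] or
#'   [compare_from_summary()].
#' @param d_min effect-size threshold (default 0.8, "large").
#' @param aoi1_only restrict to AoI-1 items (default TRUE).
#' @return character vector of item ids.
#' @export
select_panel <- function(comparisons, d_min = 0.8, aoi1_only = TRUE) {
  rows <- comparisons[!is.na(comparisons$role), , drop = FALSE]
  if (aoi1_only) rows <- rows[rows$role == "aoi1", , drop = FALSE]
  panel <- rows$item[rows$d > d_min]
  if (!length(panel))
    gf_stop(sprintf("no items with d > %g: panel is empty", d_min),
            "gf_panel_empty")
  panel
}
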