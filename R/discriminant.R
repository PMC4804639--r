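# Count-over-cutoff panel classifier.
#
# A participant is labelled ASD at count threshold k when at least k of the
# panel's directional cutoff rules are met. The printed threshold labels
# ">N" denote "at least N items met": that is the only reading under which
# the published breakdown counts reproduce every printed sensitivity row
# (20/21 = 95.2% at N = 1), so the accompanying prose "more than N items"
# is treated as loose wording. This is the single most consequential
# interpretation in the package.
#
# Likelihood ratios in the report columns are computed from the
# one-decimal-rounded sensitivity/specificity percentages (half away from
# zero), matching how such tables are printed; the exact proportions are
# kept alongside. A specificity of 1 yields an Inf PLR sentinel.

#' Number of panel items a record meets
#'
#' Strict inequalities: a value exactly at the cutoff never meets the rule.
#'
#' @param record named numeric vector (or one-row data.frame) holding the
#'   panel items' fixation percentages.
#' @param rules list of `gf_cutoff_rule`.
#' @return integer count in 0..length(rules).
#' @export
count_items_met <- function(record, rules) {
  if (is.data.frame(record)) record <- unlist(record[1, , drop = TRUE])
  met <- 0L
  for (rule in rules) {
    x <- if (rule$item %in% names(record)) record[[rule$item]] else NULL
    if (is.null(x) || is.na(x))
      gf_stop(sprintf("record is missing panel item '%s'", rule$item),
              "gf_incomplete_record")
    hit <- if (rule$direction == "asd_lower") x < rule$cutoff else x > rule$cutoff
    met <- met + as.integer(hit)
  }
  met
}

# Core metrics: tab_* are counts of participants by number-of-items-met
# (index j+1 = j items met), one vector per group.
metrics_from_met_tab <- function(tab_asd, tab_td) {
  m <- length(tab_asd) - 1L
  n1 <- sum(tab_asd); n2 <- sum(tab_td)
  if (n1 == 0L || n2 == 0L)
    gf_stop("both groups must be nonempty", "gf_insufficient_data")
  rows <- lapply(seq_len(m), function(k) {
    tp <- sum(tab_asd[(k + 1L):(m + 1L)]); fn <- n1 - tp
    fp <- sum(tab_td[(k + 1L):(m + 1L)]);  tn <- n2 - fp
    sens <- tp / n1; spec <- tn / n2
    sens_pct <- round_half_up(100 * sens, 1)
    spec_pct <- round_half_up(100 * spec, 1)
    plr <- if (spec == 1) Inf else sens / (1 - spec)
    nlr <- if (spec == 0) NA_real_ else (1 - sens) / spec
    plr_report <- if (spec_pct == 100) Inf
                  else round_half_up(sens_pct / (100 - spec_pct), 1)
    nlr_report <- if (spec_pct == 0) NA_real_
                  else round_half_up((100 - sens_pct) / spec_pct, 1)
    data.frame(k = k, tp = tp, fn = fn, tn = tn, fp = fp,
               sensitivity = sens, specificity = spec,
               sensitivity_pct = sens_pct, specificity_pct = spec_pct,
               plr = plr, nlr = nlr,
               plr_report = plr_report, nlr_report = nlr_report)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Discriminant metrics from met-count tabulations
#'
#' @param tab_asd,tab_td integer vectors of length m + 1: counts of
#'   participants by number of panel items met (0..m), per group. Accepts
#'   the output of [breakdown_met_counts()] unchanged via `tab_asd` being
#'   that list.
#' @return data.frame of [discriminant_sweep()] metrics rows.
#' @export
discriminant_from_counts <- function(tab_asd, tab_td = NULL) {
  if (is.list(tab_asd) && is.null(tab_td)) {
    tab_td <- tab_asd$td; tab_asd <- tab_asd$asd
  }
  if (length(tab_asd) != length(tab_td))
    gf_stop("met-count tabulations must have equal length", "gf_config_error")
  metrics_from_met_tab(tab_asd, tab_td)
}

combo_label <- function(mask, items) {
  if (!any(mask)) "none"
  else if (all(mask)) if (length(items) > 1) "all" else items
  else paste(items[mask], collapse = " + ")
}

#' Count-over-cutoff sweep with full breakdown
#'
#' Applies the panel's cutoff rules to every included participant, reports
#' the participant counts for each of the 2^m item combinations, and the
#' classifier metrics (sensitivity, specificity, PLR, NLR) for every count
#' threshold k = 1..m under the "at least k items met" rule.
#'
#' @param fixation a `gf_fixation_table`.
#' @param participants metadata with `participant_id`, `group`.
#' @param rules list of `gf_cutoff_rule` (the panel).
#' @return A `gf_discriminant`: list with `breakdown` (combination-level
#'   counts and group percentages), `metrics` (per-k rows), `rules`.
#' @export
discriminant_sweep <- function(fixation, participants, rules) {
  if (!length(rules)) gf_stop("rules must be nonempty", "gf_panel_empty")
  inc <- merge(fixation$included, participants[c("participant_id", "group")],
               by = "participant_id", sort = FALSE)
  if (!any(inc$group == "ASD") || !any(inc$group == "TD"))
    gf_stop("both groups must be nonempty", "gf_insufficient_data")
  m <- length(rules)
  items <- vapply(rules, `[[`, "", "item")
  hit <- sapply(rules, function(rule) {
    x <- inc[[rule$item]]
    if (is.null(x)) gf_stop(sprintf("record is missing panel item '%s'",
                                    rule$item), "gf_incomplete_record")
    if (rule$direction == "asd_lower") x < rule$cutoff else x > rule$cutoff
  })
  hit <- matrix(hit, ncol = m)
  n_met <- rowSums(hit)

  # combination breakdown: subsets ordered by size then battery order
  masks <- expand.grid(rep(list(c(FALSE, TRUE)), m))
  masks <- masks[order(rowSums(masks)), , drop = FALSE]
  breakdown <- do.call(rbind, lapply(seq_len(nrow(masks)), function(i) {
    mask <- as.logical(masks[i, ])
    sel <- apply(hit, 1, function(h) all(h == mask))
    na <- sum(sel & inc$group == "ASD"); nt <- sum(sel & inc$group == "TD")
    df <- data.frame(combo = combo_label(mask, items))
    for (j in seq_len(m)) df[[paste0("met_", items[j])]] <- as.integer(mask[j])
    df$n_asd <- na
    df$pct_asd <- round_half_up(100 * na / sum(inc$group == "ASD"), 1)
    df$n_td <- nt
    df$pct_td <- round_half_up(100 * nt / sum(inc$group == "TD"), 1)
    df
  }))
  rownames(breakdown) <- NULL

  tab <- function(g) {
    out <- integer(m + 1L)
    for (v in n_met[inc$group == g]) out[v + 1L] <- out[v + 1L] + 1L
    out
  }
  structure(list(breakdown = breakdown,
                 metrics = metrics_from_met_tab(tab("ASD"), tab("TD")),
                 rules = rules), class = "gf_discriminant")
}

#' @export
print.gf_discriminant <- function(x, ...) {
  cat(sprintf("<gf_discriminant> %d-item panel: %s\n", length(x$rules),
              paste(vapply(x$rules, `[[`, "", "item"), collapse = ", ")))
  print(x$metrics[c("k", "sensitivity_pct", "specificity_pct",
                    "plr_report", "nlr_report")], row.names = FALSE)
  invisible(x)
}
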