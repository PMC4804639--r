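# Packaged reference values from the source study's printed tables:
# demographics, per-item group fixation moments, per-item ROC summaries,
# the three-item panel breakdown, and the printed discriminant rows.

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "gazeclass")
  if (!nzchar(p)) p <- file.path("inst", "extdata", file)  # pre-install fallback
  if (!file.exists(p))
    gf_stop(sprintf("packaged fixture not found: %s", file), "gf_config_error")
  p
}

read_fixture_csv <- function(file) {
  utils::read.csv(fixture_path(file), stringsAsFactors = FALSE,
                  check.names = FALSE)
}

#' Load the packaged reference tables
#'
#' Returns the study's printed summary tables as data frames:
#' * `table1` - group demographics (age, IQ, SRS means/SDs and group sizes),
#' * `table2` - per-item group fixation means/SDs with printed t, p and
#'   Cohen's d (first row is the session availability comparison),
#' * `table4` - per-item AUC, 95% CI, cutoff direction and printed integer
#'   cutoff,
#' * `table5` - the three-item panel breakdown: participant counts per
#'   combination of items meeting their cutoffs,
#' * `table6` - the printed count-threshold discriminant rows
#'   (sensitivity, specificity, PLR, NLR).
#'
#' Convenience scalars are attached alongside: enrolled and analysed group
#' sizes, the availabilities of the excluded participants, and covariate
#' sample sizes.
#'
#' @return A named list of data frames plus scalar metadata.
#' @export
load_fixtures <- function() {
  fx <- list(
    table1 = read_fixture_csv("table1_demographics.csv"),
    table2 = read_fixture_csv("table2_fixation.csv"),
    table4 = read_fixture_csv("table4_roc.csv"),
    table5 = read_fixture_csv("table5_breakdown.csv"),
    table6 = read_fixture_csv("table6_discriminant.csv"),
    n_asd_enrolled = 26L,
    n_asd = 21L,
    n_td = 35L,
    srs_asd_n = 17L,
    srs_missing_asd = 4L,
    fsiq_asd_n = 20L,
    excluded_availability = c(60, 58, 53, 52, 31)
  )
  stopifnot(sum(fx$table5$n_asd) == fx$n_asd, sum(fx$table5$n_td) == fx$n_td)
  fx
}

#' Tabulate the panel breakdown by number of items met
#'
#' Collapses a combination-level breakdown (one row per subset of panel
#' items, indicator columns named `met_<item>`) to counts of participants
#' by how many items they met, 0..m.
#'
#' @param breakdown data.frame with `met_*` indicator columns and
#'   `n_asd` / `n_td` counts (such as `load_fixtures()$table5`).
#' @return list with integer vectors `asd` and `td`, each of length m + 1
#'   (index j + 1 holds the count of participants meeting j items).
#' @export
breakdown_met_counts <- function(breakdown) {
  met_cols <- grep("^met_", names(breakdown), value = TRUE)
  if (length(met_cols) == 0L)
    gf_stop("breakdown has no 'met_' indicator columns", "gf_config_error")
  m <- length(met_cols)
  n_met <- rowSums(breakdown[met_cols])
  tab <- function(counts) {
    out <- integer(m + 1L)
    for (i in seq_along(n_met)) out[n_met[i] + 1L] <- out[n_met[i] + 1L] + counts[i]
    out
  }
  list(asd = tab(breakdown$n_asd), td = tab(breakdown$n_td))
}
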