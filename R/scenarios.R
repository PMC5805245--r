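# Policy-scenario engine: timed transference-rate overrides applied on top
# of a baseline table, and baseline-vs-scenario comparison of projections.

#' Policy-scenario specification
#'
#' A list of timed overrides of transference rates. Each override raises
#' one rate to a floor value for a set of age groups over a calendar
#' window: while `from <= t <= to` the effective rate is
#' `max(baseline, value)` (an intervention "increases the rate to" the
#' stated value; already-larger baselines are kept).
#'
#' @param overrides List of overrides, each a list with elements
#'   `age_groups` (labels), `tau` (one of `"tau1"`..`"tau4"`), `value`
#'   (fraction/year in `[0, 1]`), `from`, `to` (calendar years).
#' @param label Scenario name.
#' @return List of class `"scenario_spec"`.
#' @examples
#' # school-age intervention: raise recovery rates to 0.02 during 2011-2030
#' scenario_spec(list(
#'   list(age_groups = c("5-9", "10-14"), tau = "tau3", value = 0.02,
#'        from = 2011, to = 2030),
#'   list(age_groups = c("5-9", "10-14"), tau = "tau4", value = 0.02,
#'        from = 2011, to = 2030)
#' ), label = "school-age recovery")
#' @export
scenario_spec <- function(overrides, label = "scenario") {
  for (ov in overrides) {
    if (!all(c("age_groups", "tau", "value", "from", "to") %in% names(ov))) {
      stop("each override needs age_groups, tau, value, from, to",
           call. = FALSE)
    }
    if (!ov$tau %in% paste0("tau", 1:4)) {
      stop("unknown rate name: ", ov$tau, call. = FALSE)
    }
    if (ov$value < 0 || ov$value > 1) {
      stop("override value must be in [0, 1]", call. = FALSE)
    }
    if (ov$from > ov$to) stop("override has from > to", call. = FALSE)
    if (!all(ov$age_groups %in% age_group_labels(13))) {
      stop("unknown age group(s): ",
           paste(setdiff(ov$age_groups, age_group_labels(13)), collapse = ", "),
           call. = FALSE)
    }
  }
  structure(list(overrides = overrides, label = label),
            class = "scenario_spec")
}

#' Effective transference rates at a point in time under a scenario
#'
#' Applies every override whose window contains `t` to the baseline table
#' (floor semantics, see [scenario_spec()]); outside all windows the
#' baseline is returned unchanged. The overridden table must remain
#' feasible (`tau2 + tau4 <= 1`).
#'
#' @param rates Baseline [tr_table()].
#' @param spec A [scenario_spec()] (or `NULL` for baseline).
#' @param t Calendar year.
#' @return The effective [tr_table()] at `t`.
#' @export
apply_scenario <- function(rates, spec, t) {
  if (is.null(spec)) return(rates)
  stopifnot(inherits(spec, "scenario_spec"))
  out <- rates
  for (ov in spec$overrides) {
    if (t < ov$from || t > ov$to) next
    rows <- out$age_group %in% ov$age_groups
    out[[ov$tau]][rows] <- pmax(out[[ov$tau]][rows], ov$value)
  }
  validate_tr_table(out)
  out
}

#' Compare a scenario projection against its baseline
#'
#' For each BMI category, the pooled prevalence over the given age groups
#' at `year` in both runs, the difference in prevalence points, and the
#' relative change in percent (negative = the scenario lowered the
#' prevalence). Both metrics are reported because "decreased by x%" is
#' ambiguous between them; the relative change is the headline.
#'
#' @param baseline,scenario `projection` objects on the same calendar and
#'   age coverage.
#' @param age_groups Age-group labels to pool.
#' @param year Report year.
#' @return Data frame with columns `category`, `baseline`, `scenario`,
#'   `diff_points`, `rel_change_pct`.
#' @export
compare_projections <- function(baseline, scenario,
                                age_groups = age_group_labels(),
                                year) {
  ylist <- intersect(unique(baseline$year), unique(scenario$year))
  if (!year %in% ylist) {
    stop("year ", year, " not present in both runs", call. = FALSE)
  }
  pb <- pooled_prevalence(baseline, year, age_groups)
  ps <- pooled_prevalence(scenario, year, age_groups)
  data.frame(
    category = bmi_categories(),
    baseline = as.numeric(pb),
    scenario = as.numeric(ps),
    diff_points = as.numeric(ps - pb),
    rel_change_pct = as.numeric(ifelse(pb > 0, 100 * (ps - pb) / pb, 0)),
    stringsAsFactors = FALSE
  )
}
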