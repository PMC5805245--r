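# Parallel simulation of the three socioeconomic strata, the obesity
# prevalence ratio between the lower and higher strata, and per-stratum
# transference-rate summaries.

#' Run the model for several SES strata in parallel
#'
#' Each stratum is an independent aging chain (no flows between strata)
#' run on a shared calendar; the pooled output aggregates counts across
#' strata, so pooled prevalence is the population-weighted mean of the
#' per-stratum prevalences.
#'
#' @param initials Named list of [population_state()] objects, one per
#'   stratum (names are the stratum labels).
#' @param tr_tables A single [tr_table()] holding rows for every stratum,
#'   or a named list of per-stratum tables.
#' @param demos A single [demography()] shared by all strata, or a named
#'   list of per-stratum demographies (strata missing from the list fall
#'   back to the element named `"all"` when present).
#' @param t0,t1,dt,method,formulation,scenario Passed to
#'   [run_projection()].
#' @return List of class `"stratified_run"`: `strata` (named list of
#'   projections) and `pooled` (projection-shaped data frame with
#'   `ses = "pooled"`).
#' @export
run_stratified <- function(initials, tr_tables, demos, t0, t1, dt = 0.25,
                           method = "euler", formulation = "stock_outflow",
                           scenario = NULL) {
  stopifnot(is.list(initials), length(names(initials)) == length(initials))
  strata <- names(initials)
  get_rates <- function(s) {
    if (inherits(tr_tables, "tr_table")) {
      sub <- tr_tables[tr_tables$ses == s, , drop = FALSE]
      if (nrow(sub) == 0L) stop("no TR rows for stratum ", s, call. = FALSE)
      class(sub) <- c("tr_table", "data.frame")
      sub
    } else {
      tbl <- tr_tables[[s]] %||% stop("missing TR table for stratum ", s,
                                      call. = FALSE)
      tbl
    }
  }
  get_demo <- function(s) {
    if (inherits(demos, "demography")) demos
    else demos[[s]] %||% demos[["all"]] %||%
      stop("missing demography for stratum ", s, call. = FALSE)
  }
  runs <- lapply(strata, function(s) {
    run_projection(initials[[s]], get_rates(s), get_demo(s), t0, t1,
                   dt = dt, method = method, formulation = formulation,
                   scenario = scenario)
  })
  names(runs) <- strata
  pooled <- runs[[1L]][, c("year", "age_group", "category")]
  pooled$count <- Reduce(`+`, lapply(runs, `[[`, "count"))
  tot <- stats::ave(pooled$count, pooled$year, pooled$age_group, FUN = sum)
  pooled$prevalence <- pooled$count / pmax(tot, .Machine$double.xmin)
  pooled <- data.frame(year = pooled$year, ses = "pooled",
                       age_group = pooled$age_group,
                       category = pooled$category,
                       count = pooled$count, prevalence = pooled$prevalence,
                       stringsAsFactors = FALSE)
  structure(list(strata = runs, pooled = pooled), class = "stratified_run")
}

#' @export
print.stratified_run <- function(x, ...) {
  yrs <- range(x$pooled$year)
  cat("<stratified_run>", length(x$strata), "strata (",
      paste(names(x$strata), collapse = ", "), "), years", yrs[1], "-",
      yrs[2], "\n")
  invisible(x)
}

#' Obesity prevalence ratio between the lower and higher strata
#'
#' Adult (ages 20-59) obesity prevalence of the lower-SES stratum divided
#' by that of the higher-SES stratum. A value above 1 means the obesity
#' burden sits with the lower-SES population.
#'
#' @param run A [run_stratified()] result containing `"lower"` and
#'   `"higher"` strata.
#' @param year Report year(s); default: every year in the run.
#' @return Data frame with columns `year`, `pr`.
#' @export
prevalence_ratio <- function(run, year = NULL) {
  stopifnot(inherits(run, "stratified_run"))
  if (!all(c("lower", "higher") %in% names(run$strata))) {
    stop("prevalence_ratio needs 'lower' and 'higher' strata", call. = FALSE)
  }
  adult <- age_group_labels()[5:12] # 20-24 .. 55-59
  years <- if (is.null(year)) sort(unique(run$pooled$year)) else year
  pr <- vapply(years, function(y) {
    ob <- vapply(c("lower", "higher"), function(s) {
      pooled_prevalence(run$strata[[s]], y, adult)[["obese"]]
    }, numeric(1))
    if (ob[["higher"]] <= 0) {
      stop("higher-SES obesity prevalence is zero in ", y,
           "; ratio undefined", call. = FALSE)
    }
    ob[["lower"]] / ob[["higher"]]
  }, numeric(1))
  data.frame(year = years, pr = pr)
}

#' Mean transference rate of a stratum
#'
#' Unweighted arithmetic mean of one transference-rate column across the
#' twelve age groups of a stratum — the aggregation behind per-stratum
#' headline rates such as "mean TR from not overweight to overweight".
#'
#' @param table A [tr_table()].
#' @param ses Stratum label present in the table.
#' @param which One of `"tau1"`, `"tau2"`, `"tau3"`, `"tau4"`.
#' @return Mean rate (fraction per year).
#' @export
mean_tr <- function(table, ses, which = c("tau1", "tau2", "tau3", "tau4")) {
  which <- match.arg(which)
  validate_tr_table(table)
  sub <- table[table$ses == ses, , drop = FALSE]
  if (nrow(sub) != N_GROUPS) {
    stop("stratum ", ses, " has ", nrow(sub), " rows; expected ", N_GROUPS,
         call. = FALSE)
  }
  mean(sub[[which]])
}
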