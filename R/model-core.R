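#' BMI category labels, in the fixed order used by all vectors and matrices
#'
#' All prevalence vectors, stock matrices and transition matrices in the
#' package use these three categories in this order.
#'
#' @return Character vector `c("not_overweight", "overweight", "obese")`.
#' @export
bmi_categories <- function() {
  c("not_overweight", "overweight", "obese")
}

#' Five-year age-group labels
#'
#' The simulated population covers ages 0-59 in twelve 5-year groups;
#' individuals exit the system at age 60. The optional thirteenth band
#' "60-64" exists only as an estimation target (the wave-2 ages a cohort
#' aged 55-59 at wave 1 has reached five years later).
#'
#' @param n Number of groups: 12 (simulated bands) or 13 (adds "60-64").
#' @return Character vector of labels `"0-4"`, `"5-9"`, ..., `"55-59"`
#'   (and `"60-64"` when `n = 13`).
#' @export
age_group_labels <- function(n = 12) {
  stopifnot(n %in% c(12L, 13L))
  lo <- 5L * (seq_len(n) - 1L)
  paste0(lo, "-", lo + 4L)
}

#' Socioeconomic stratum labels
#'
#' Wealth-index quintiles 1-2, 3 and 4-5 grouped into three strata, or
#' `"all"` for an unstratified run. No transitions occur between strata.
#'
#' @return Character vector `c("lower", "middle", "higher")`.
#' @export
ses_levels <- function() {
  c("lower", "middle", "higher")
}

#' Number of simulated age groups
#' @keywords internal
N_GROUPS <- 12L

#' Years of residence per age group
#' @keywords internal
Y_RESIDENCE <- 5

ages_of_group <- function(i) {
  # i is 0-based group index; returns the five single years of age it spans
  5L * i + 0:4
}

#' Survival fraction over the residence time of an age group
#'
#' Fraction of an age group's members surviving the `Y`-year residence in
#' the group given a constant per-year mortality rate `R`:
#' `S = exp(-R * Y)`. At `R = 0` the fraction is 1; it decreases
#' monotonically in both `R` and `Y`.
#'
#' @param R Per-year mortality rate(s), `>= 0`.
#' @param Y Residence time in years, `> 0` (default 5).
#' @return Survival fraction(s) in `(0, 1]`, same length as `R`.
#' @examples
#' survival_fraction(0)          # 1
#' survival_fraction(0.01, 5)    # exp(-0.05)
#' @export
survival_fraction <- function(R, Y = Y_RESIDENCE) {
  if (!is.numeric(R) || any(!is.finite(R)) || any(R < 0)) {
    stop("mortality rate `R` must be finite and >= 0", call. = FALSE)
  }
  if (!is.numeric(Y) || length(Y) != 1L || !is.finite(Y) || Y <= 0) {
    stop("residence time `Y` must be a single positive number", call. = FALSE)
  }
  exp(-R * Y)
}

#' Transference-rate table
#'
#' One row per (SES stratum, age group): the four annual transference rates
#' between adjacent BMI categories. `tau1` moves not-overweight ->
#' overweight, `tau2` overweight -> obese, `tau3` obese -> overweight and
#' `tau4` overweight -> not-overweight. The implied retention rates are
#' `alpha1 = 1 - tau1`, `alpha2 = 1 - tau2 - tau4`, `alpha3 = 1 - tau3`,
#' so feasibility requires every rate in `[0, 1]` and `tau2 + tau4 <= 1`.
#'
#' @param tau1,tau2,tau3,tau4 Numeric vectors of length 12 (fractions/year).
#' @param ses Stratum label for all rows (default `"all"`).
#' @param age_group Age-group labels (default [age_group_labels()]).
#' @return A `data.frame` of class `"tr_table"` with columns
#'   `ses, age_group, tau1, tau2, tau3, tau4`.
#' @export
tr_table <- function(tau1, tau2, tau3, tau4, ses = "all",
                     age_group = age_group_labels()) {
  n <- length(age_group)
  stopifnot(length(tau1) == n, length(tau2) == n,
            length(tau3) == n, length(tau4) == n)
  out <- data.frame(
    ses = rep_len(ses, n), age_group = age_group,
    tau1 = as.numeric(tau1), tau2 = as.numeric(tau2),
    tau3 = as.numeric(tau3), tau4 = as.numeric(tau4),
    stringsAsFactors = FALSE
  )
  class(out) <- c("tr_table", "data.frame")
  validate_tr_table(out)
  out
}

#' Validate a transference-rate table
#'
#' Checks rate ranges (`0 <= tau <= 1`), the joint overweight-exit
#' constraint `tau2 + tau4 <= 1`, and column completeness.
#'
#' @param x A `tr_table` (or plain data.frame with the same columns).
#' @param tol Numerical slack for the constraints (default 1e-9).
#' @return `x`, invisibly; errors describe every violated rule.
#' @export
validate_tr_table <- function(x, tol = 1e-9) {
  needed <- c("ses", "age_group", "tau1", "tau2", "tau3", "tau4")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols)) {
    stop("tr_table is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  taus <- as.matrix(x[, c("tau1", "tau2", "tau3", "tau4")])
  if (any(!is.finite(taus))) stop("tr_table has non-finite rates", call. = FALSE)
  if (any(taus < -tol | taus > 1 + tol)) {
    stop("tr_table has rates outside [0, 1]", call. = FALSE)
  }
  if (any(x$tau2 + x$tau4 > 1 + tol)) {
    stop("tr_table violates tau2 + tau4 <= 1", call. = FALSE)
  }
  invisible(x)
}

#' Retention rates implied by a transference-rate table
#'
#' @param x A `tr_table`.
#' @return Data frame with `ses`, `age_group`, `alpha1`, `alpha2`, `alpha3`.
#' @export
retention_rates <- function(x) {
  validate_tr_table(x)
  data.frame(
    ses = x$ses, age_group = x$age_group,
    alpha1 = 1 - x$tau1,
    alpha2 = 1 - x$tau2 - x$tau4,
    alpha3 = 1 - x$tau3,
    stringsAsFactors = FALSE
  )
}

#' Demographic parameter set
#'
#' Holds the demographic inputs of the aging chain: population and
#' mortality by 5-year age group, a fertility time series, the female
#' fraction of the childbearing-age population, and the birth fractions by
#' BMI category.
#'
#' @param pop Numeric vector of 12 population sizes (people) by age group.
#' @param mortality Numeric vector of 12 per-year mortality rates `R_i`.
#' @param fertility Data frame with columns `year`, `f` (children per
#'   woman); looked up piecewise-constant by calendar year, no
#'   extrapolation outside its range.
#' @param mu Fraction of the population aged 15-49 that is female
#'   (default 0.523, the urban female fraction in the 2005 ENDS).
#' @param theta Length-3 birth fractions by BMI category (must sum to 1);
#'   the prevalences by category of children aged 0-2 months.
#' @param Y Residence time per age group in years (default 5).
#' @param YI,YF First and last childbearing ages (defaults 15 and 49).
#' @return A list of class `"demography"`.
#' @export
demography <- function(pop, mortality, fertility, mu = 0.523,
                       theta = c(not_overweight = 0.93, overweight = 0.05,
                                 obese = 0.02),
                       Y = Y_RESIDENCE, YI = 15, YF = 49) {
  stopifnot(length(pop) == N_GROUPS, length(mortality) == N_GROUPS)
  if (any(!is.finite(pop)) || any(pop < 0)) {
    stop("populations must be finite and >= 0", call. = FALSE)
  }
  if (any(!is.finite(mortality)) || any(mortality < 0)) {
    stop("mortality rates must be finite and >= 0", call. = FALSE)
  }
  if (!is.data.frame(fertility) || !all(c("year", "f") %in% names(fertility))) {
    stop("fertility must be a data.frame with columns year, f", call. = FALSE)
  }
  if (any(fertility$f < 0)) stop("fertility must be >= 0", call. = FALSE)
  if (mu < 0 || mu > 1) stop("mu must be in [0, 1]", call. = FALSE)
  theta <- as.numeric(theta)
  if (length(theta) != 3L || abs(sum(theta) - 1) > 1e-9 || any(theta < 0)) {
    stop("theta must be 3 non-negative birth fractions summing to 1",
         call. = FALSE)
  }
  structure(
    list(pop = as.numeric(pop), mortality = as.numeric(mortality),
         fertility = fertility[order(fertility$year), c("year", "f")],
         mu = mu, theta = stats::setNames(theta, bmi_categories()),
         Y = Y, YI = YI, YF = YF,
         S = survival_fraction(as.numeric(mortality), Y)),
    class = "demography"
  )
}

#' @export
print.demography <- function(x, ...) {
  cat("<demography> 12 age groups, total population",
      format(sum(x$pop), big.mark = ","), "\n")
  cat("  mu =", x$mu, "; theta =", paste(signif(x$theta, 3), collapse = "/"),
      "; fertility", min(x$fertility$year), "-", max(x$fertility$year), "\n")
  invisible(x)
}

#' Fertility-rate lookup
#'
#' Piecewise-constant lookup of the fertility series by calendar year.
#' Years between tabulated points take the last tabulated value at or
#' before `t`; years outside the series range are an error (no implicit
#' extrapolation).
#'
#' @param demo A [demography()] object.
#' @param t Calendar time (years; fractional times use `floor(t)`).
#' @return Fertility rate (children per woman) at `t`.
#' @export
fertility_at <- function(demo, t) {
  yr <- floor(t)
  fs <- demo$fertility
  if (yr < min(fs$year) || yr > max(fs$year)) {
    stop(sprintf("year %s outside fertility series (%d-%d); no extrapolation",
                 format(t), min(fs$year), max(fs$year)), call. = FALSE)
  }
  fs$f[findInterval(yr, fs$year)]
}

#' Survey prevalence table for one wave and one stratum
#'
#' Prevalences of the three BMI categories at each single year of age
#' 0-64. Each age's prevalences must lie on the 3-simplex.
#'
#' Ages not covered by the survey may be left as all-`NA` columns (they are
#' rejected by the simulator initializer but tolerated by
#' [estimate_all()]'s `allow_partial` mode).
#'
#' @param wave Survey year (e.g. 2005).
#' @param P 3 x 65 numeric matrix, rows in [bmi_categories()] order,
#'   columns ages 0..64.
#' @param ses Stratum label (default `"all"`).
#' @return A list of class `"survey_prevalence"` with elements `wave`,
#'   `ses` and `P` (dimnames set).
#' @export
survey_prevalence <- function(wave, P, ses = "all") {
  P <- as.matrix(P)
  if (nrow(P) != 3L || ncol(P) != 65L) {
    stop("P must be 3 x 65 (categories x ages 0..64)", call. = FALSE)
  }
  dimnames(P) <- list(bmi_categories(), 0:64)
  all_na <- colSums(is.na(P)) == 3L
  obs <- P[, !all_na, drop = FALSE]
  if (any(!is.finite(obs)) || any(obs < -1e-12)) {
    stop("prevalences must be finite and >= 0 (missing ages must be all-NA)",
         call. = FALSE)
  }
  bad <- which(!all_na)[abs(colSums(obs) - 1) > 1e-9]
  if (length(bad)) {
    stop("prevalences at age(s) ", paste(bad - 1L, collapse = ", "),
         " do not sum to 1", call. = FALSE)
  }
  structure(list(wave = wave, ses = ses, P = P), class = "survey_prevalence")
}

#' @export
print.survey_prevalence <- function(x, ...) {
  cat("<survey_prevalence> wave", x$wave, "ses", x$ses, "- ages 0-64\n")
  print(round(x$P[, c(1, 21, 41, 61)], 3))
  invisible(x)
}

#' Population state: stocks by age group and BMI category
#'
#' @param stocks 12 x 3 matrix of people (rows = age groups, columns =
#'   BMI categories).
#' @param year Calendar year of the state.
#' @param ses Stratum label.
#' @return A matrix of class `"population_state"` with attributes `year`
#'   and `ses`.
#' @export
population_state <- function(stocks, year, ses = "all") {
  stocks <- as.matrix(stocks)
  stopifnot(nrow(stocks) == N_GROUPS, ncol(stocks) == 3L)
  if (any(!is.finite(stocks)) || any(stocks < 0)) {
    stop("stocks must be finite and >= 0", call. = FALSE)
  }
  dimnames(stocks) <- list(age_group_labels(), bmi_categories())
  structure(stocks, year = year, ses = ses,
            class = c("population_state", "matrix", "array"))
}

#' @export
print.population_state <- function(x, ...) {
  cat("<population_state> year", attr(x, "year"), "ses", attr(x, "ses"),
      "- total", format(round(sum(x)), big.mark = ","), "people\n")
  print(round(unclass(x)))
  invisible(x)
}

#' Initialize stocks from survey prevalences and group populations
#'
#' Each age group's population is split across the BMI categories in
#' proportion to the group's band prevalence, i.e. the mean over its five
#' single-year prevalences — unweighted by default, or weighted by a
#' supplied within-band age distribution.
#'
#' @param prev A [survey_prevalence()] object.
#' @param pop_by_group Numeric vector of 12 group populations.
#' @param age_weights Optional 12 x 5 matrix of within-band weights (rows
#'   normalized internally); default unweighted.
#' @return A [population_state()] for `prev$wave`.
#' @export
stocks_from_prevalence <- function(prev, pop_by_group, age_weights = NULL) {
  stopifnot(inherits(prev, "survey_prevalence"),
            length(pop_by_group) == N_GROUPS)
  if (any(pop_by_group < 0)) stop("populations must be >= 0", call. = FALSE)
  stocks <- matrix(0, N_GROUPS, 3L)
  for (i in seq_len(N_GROUPS) - 1L) {
    cols <- ages_of_group(i) + 1L
    w <- if (is.null(age_weights)) rep(1 / 5, 5) else {
      wi <- age_weights[i + 1L, ]
      wi / sum(wi)
    }
    band_prev <- as.numeric(prev$P[, cols] %*% w)
    stocks[i + 1L, ] <- pop_by_group[i + 1L] * band_prev
  }
  population_state(stocks, year = prev$wave, ses = prev$ses)
}

#' Per-group prevalences of a population state
#'
#' @param state A [population_state()].
#' @return 12 x 3 matrix of prevalences; rows sum to 1 (rows with zero
#'   population return NA).
#' @export
state_prevalence <- function(state) {
  tot <- rowSums(state)
  sweep(unclass(state), 1, tot, "/")
}
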