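# Stock-and-flow engine for one population stratum: births, BMI-category
# transfers, aging-chain exits, and fixed-step time integration.

# rows (0-based groups 3..9) covering ages 15-49
CHILDBEARING_ROWS <- 4:10

tau_matrix <- function(rates, ses = "all") {
  validate_tr_table(rates)
  sub <- rates[rates$ses == ses, , drop = FALSE]
  if (nrow(sub) == 0L && length(unique(rates$ses)) == 1L) {
    sub <- rates # single-stratum table used for any label
  }
  sub <- sub[match(age_group_labels(), sub$age_group), , drop = FALSE]
  if (anyNA(sub$tau1)) {
    stop("tr_table lacks rows for all 12 simulated age groups (ses = ",
         ses, ")", call. = FALSE)
  }
  m <- as.matrix(sub[, c("tau1", "tau2", "tau3", "tau4")])
  rownames(m) <- age_group_labels()
  m
}

#' Births per year by BMI category
#'
#' `B_c = mu * theta_c * (f(t) / (YF - YI + 1)) * sum over childbearing-age
#' groups of (N + W + O)`: the female childbearing-age population times the
#' fertility rate spread uniformly over the `YF - YI + 1 = 35` childbearing
#' years, split across categories by the birth fractions `theta`.
#'
#' @param state A [population_state()].
#' @param demo A [demography()] object.
#' @param t Calendar year (fertility is looked up piecewise-constant).
#' @return Named length-3 vector of births (people/year) by category.
#' @export
births <- function(state, demo, t) {
  cb_pop <- sum(state[CHILDBEARING_ROWS, ])
  f <- fertility_at(demo, t)
  total <- demo$mu * cb_pop * f / (demo$YF - demo$YI + 1)
  stats::setNames(total * demo$theta, bmi_categories())
}

transfer_net <- function(stocks, taus) {
  # net within-group category flows, people/year; rows = groups, cols = N,W,O
  N <- stocks[, 1]; W <- stocks[, 2]; O <- stocks[, 3]
  t1 <- taus[, 1]; t2 <- taus[, 2]; t3 <- taus[, 3]; t4 <- taus[, 4]
  cbind(t4 * W - t1 * N,
        t1 * N + t3 * O - (t2 + t4) * W,
        t2 * W - t3 * O)
}

#' Exit rates by age group and BMI category
#'
#' Under the default `"stock_outflow"` formulation the exit rate of each
#' stock is first-order: `E = stock / Y`, the standard aging-chain outflow;
#' a fraction `S_i` of it matures into the next group and `1 - S_i` dies.
#' The `"literal_paper"` formulation instead sets each exit rate to the
#' group's net inflow divided by `Y` (births/maturation plus net category
#' transfers), a form under which stocks never drain (with zero births and
#' transfers the exit is zero regardless of the stock); it is retained for
#' fidelity experiments only.
#'
#' @param state A [population_state()].
#' @param rates A [tr_table()].
#' @param demo A [demography()].
#' @param births_vec Length-3 births vector (from [births()]).
#' @param formulation `"stock_outflow"` (default) or `"literal_paper"`.
#' @return 12 x 3 matrix of exit rates (people/year).
#' @export
exit_rates <- function(state, rates, demo, births_vec,
                       formulation = c("stock_outflow", "literal_paper")) {
  formulation <- match.arg(formulation)
  taus <- tau_matrix(rates, attr(state, "ses") %||% "all")
  if (formulation == "stock_outflow") {
    E <- unclass(state) / demo$Y
  } else {
    tr <- transfer_net(unclass(state), taus)
    E <- matrix(0, N_GROUPS, 3L)
    E[1, ] <- (births_vec + tr[1, ]) / demo$Y
    for (i in 2:N_GROUPS) {
      E[i, ] <- (E[i - 1, ] * demo$S[i - 1] + tr[i, ]) / demo$Y
    }
  }
  dimnames(E) <- list(age_group_labels(), bmi_categories())
  E
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Net rate of change of every stock
#'
#' The derivative of each (age group, category) stock: births into group
#' 0-4 (or maturation inflow `E_{i-1} * S_{i-1}` for later groups), plus
#' net category transfers (`N` loses `tau1*N`, gains `tau4*W`; `W` gains
#' `tau1*N + tau3*O`, loses `(tau2+tau4)*W`; `O` gains `tau2*W`, loses
#' `tau3*O`), minus the group's exit rate.
#'
#' @inheritParams exit_rates
#' @param t Calendar year.
#' @return 12 x 3 matrix of derivatives (people/year).
#' @export
net_derivative <- function(state, rates, demo, t,
                           formulation = c("stock_outflow", "literal_paper")) {
  formulation <- match.arg(formulation)
  if (any(unclass(state) < 0)) stop("negative stock input", call. = FALSE)
  taus <- tau_matrix(rates, attr(state, "ses") %||% "all")
  B <- births(state, demo, t)
  E <- exit_rates(state, rates, demo, B, formulation)
  tr <- transfer_net(unclass(state), taus)
  inflow <- rbind(B, E[-N_GROUPS, ] * demo$S[-N_GROUPS])
  d <- inflow + tr - E
  dimnames(d) <- list(age_group_labels(), bmi_categories())
  d
}

raw_derivative <- function(stocks, taus, demo, t, formulation) {
  # unclassed fast path used by the integrator; stocks clamped at 0 for flows
  s <- pmax(stocks, 0)
  cb_pop <- sum(s[CHILDBEARING_ROWS, ])
  f <- fertility_at(demo, t)
  B <- demo$mu * cb_pop * f / (demo$YF - demo$YI + 1) * demo$theta
  tr <- transfer_net(s, taus)
  if (formulation == "stock_outflow") {
    E <- s / demo$Y
  } else {
    E <- matrix(0, N_GROUPS, 3L)
    E[1, ] <- (B + tr[1, ]) / demo$Y
    for (i in 2:N_GROUPS) E[i, ] <- (E[i - 1, ] * demo$S[i - 1] + tr[i, ]) / demo$Y
  }
  rbind(B, E[-N_GROUPS, ] * demo$S[-N_GROUPS]) + tr - E
}

#' Project the population forward in time
#'
#' Fixed-step integration of the stock-and-flow system from `t0` to `t1`,
#' reporting stocks and per-group prevalences at every integer year.
#' Negative excursions (possible at coarse steps) are clamped to zero after
#' each step and counted.
#'
#' @param initial A [population_state()] at `t0`.
#' @param rates A [tr_table()] (baseline rates).
#' @param demo A [demography()].
#' @param t0,t1 Start and end calendar years (`t1 > t0`).
#' @param dt Step size in years (default 0.25).
#' @param method `"euler"` (default) or `"rk4"`.
#' @param formulation Exit-rate formulation, see [exit_rates()].
#' @param scenario Optional [scenario_spec()] of timed TR overrides.
#' @return A `data.frame` of class `"projection"` with columns
#'   `year, ses, age_group, category, count, prevalence`; attributes
#'   `final_state` (the end-of-run [population_state()]) and
#'   `clamped` (number of clamped stock excursions).
#' @export
run_projection <- function(initial, rates, demo, t0, t1, dt = 0.25,
                           method = c("euler", "rk4"),
                           formulation = c("stock_outflow", "literal_paper"),
                           scenario = NULL) {
  method <- match.arg(method)
  formulation <- match.arg(formulation)
  stopifnot(inherits(initial, "population_state"), t1 > t0, dt > 0)
  ses <- attr(initial, "ses")
  base_taus <- tau_matrix(rates, ses)
  taus_at <- function(t) {
    if (is.null(scenario)) base_taus
    else tau_matrix(apply_scenario(rates, scenario, t), ses)
  }
  n_steps <- ceiling((t1 - t0) / dt - 1e-9)
  stocks <- unclass(initial)
  clamped <- 0L
  records <- vector("list", floor(t1 - t0) + 1L)
  rec_i <- 1L
  record <- function(t, s) {
    prev <- s / pmax(rowSums(s), .Machine$double.xmin)
    data.frame(
      year = t, ses = ses,
      age_group = rep(age_group_labels(), 3L),
      category = rep(bmi_categories(), each = N_GROUPS),
      count = as.vector(s), prevalence = as.vector(prev),
      stringsAsFactors = FALSE
    )
  }
  t <- t0
  if (abs(t - round(t)) < 1e-9) { records[[rec_i]] <- record(round(t), stocks); rec_i <- rec_i + 1L }
  for (k in seq_len(n_steps)) {
    h <- min(dt, t1 - t)
    taus <- taus_at(t)
    if (method == "euler") {
      stocks_new <- stocks + h * raw_derivative(stocks, taus, demo, t, formulation)
    } else {
      k1 <- raw_derivative(stocks, taus, demo, t, formulation)
      k2 <- raw_derivative(stocks + h / 2 * k1, taus_at(t + h / 2), demo, t + h / 2, formulation)
      k3 <- raw_derivative(stocks + h / 2 * k2, taus_at(t + h / 2), demo, t + h / 2, formulation)
      k4 <- raw_derivative(stocks + h * k3, taus_at(t + h), demo, t + h, formulation)
      stocks_new <- stocks + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    if (any(!is.finite(stocks_new))) {
      stop(sprintf("non-finite state at t = %.3f; aborting integration", t),
           call. = FALSE)
    }
    neg <- stocks_new < 0
    if (any(neg)) {
      clamped <- clamped + sum(neg & stocks_new < -1e-9)
      stocks_new[neg] <- 0
    }
    stocks <- stocks_new
    t <- t + h
    if (abs(t - round(t)) < 1e-6 && round(t) <= t1 + 1e-9) {
      records[[rec_i]] <- record(round(t), stocks)
      rec_i <- rec_i + 1L
    }
  }
  out <- do.call(rbind, records[seq_len(rec_i - 1L)])
  class(out) <- c("projection", "data.frame")
  attr(out, "final_state") <- population_state(pmax(stocks, 0), year = t1, ses = ses)
  attr(out, "clamped") <- clamped
  attr(out, "dt") <- dt
  attr(out, "method") <- method
  if (clamped > 0L) {
    message(sprintf("run_projection: clamped %d negative stock excursion(s) at 0",
                    clamped))
  }
  out
}

#' Aggregate prevalence over a set of age groups
#'
#' Pooled prevalence of each BMI category over the given age groups at one
#' report year: category count summed over groups divided by total people.
#'
#' @param proj A `projection` (from [run_projection()]).
#' @param year Report year.
#' @param age_groups Age-group labels to pool (default all 12).
#' @return Named length-3 vector of prevalences.
#' @export
pooled_prevalence <- function(proj, year, age_groups = age_group_labels()) {
  sub <- proj[proj$year == year & proj$age_group %in% age_groups, ]
  if (nrow(sub) == 0L) stop("no rows for year ", year, call. = FALSE)
  tot <- sum(sub$count)
  vapply(bmi_categories(),
         function(cc) sum(sub$count[sub$category == cc]) / tot,
         numeric(1))
}
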