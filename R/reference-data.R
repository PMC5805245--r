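# Bundled reference inputs: transference-rate estimates for the urban
# Colombian population (ENDS 2005/2010), and a synthetic reconstruction of
# the 2005 starting conditions for full-horizon projections.

#' Bundled reference transference-rate tables
#'
#' Reference estimates of the annual transference rates between BMI
#' categories for the urban Colombian population, derived from the 2005
#' and 2010 national demographic and health surveys (ENDS):
#' `"urban"` is the unstratified table (12 age groups), `"ses"` the
#' SES-stratified table (3 strata x 12 age groups).
#'
#' @param which `"urban"` or `"ses"`.
#' @return A [tr_table()].
#' @export
reference_tr_table <- function(which = c("urban", "ses")) {
  which <- match.arg(which)
  path <- system.file("extdata",
                      paste0("ends_tr_", which, ".csv"),
                      package = "nutridyn", mustWork = TRUE)
  read_tr_csv(path)
}

group_anchor_profile <- function(ow, ob) {
  # constant-within-band single-age curves from 12 group-level percentages
  P <- matrix(0, 3L, 65L)
  for (i in seq_len(N_GROUPS)) {
    cols <- 5L * (i - 1L) + 1:5
    P[2, cols] <- ow[i] / 100
    P[3, cols] <- ob[i] / 100
  }
  # ages 60-64 carried forward from the 55-59 band (initialization only)
  P[2, 61:65] <- ow[N_GROUPS] / 100
  P[3, 61:65] <- ob[N_GROUPS] / 100
  P[1, ] <- 1 - P[2, ] - P[3, ]
  dimnames(P) <- list(bmi_categories(), 0:64)
  P
}

#' Synthetic reconstruction of the 2005 Colombian starting conditions
#'
#' The published full-horizon projections start from survey prevalences by
#' single year of age and official demographic tables that are not
#' redistributable here. This function builds a synthetic stand-in: the
#' 2005 group-level overweight/obesity prevalences that are published as
#' aggregates (ages 15-39 group by group; adults 20-59 pooled at 34.2% /
#' 15.7%; per-SES adult aggregates) anchor the profile, childhood and
#' early-adult gaps are filled with plausible survey-scale values, and the
#' two oldest adult groups are solved so the pooled adult aggregates hold
#' exactly under the synthetic demography's age structure. Per-SES
#' profiles scale the pooled profile to the published per-SES adult
#' aggregates, with population shares 0.4 / 0.2 / 0.4 (wealth-index
#' quintiles 1-2, 3, 4-5).
#'
#' @return List: `prevalence` (named list of [survey_prevalence()] for
#'   `all`, `lower`, `middle`, `higher`), `demography` (shared
#'   [demography()]), `shares` (stratum population shares), `tr_urban`
#'   and `tr_ses` (the bundled [reference_tr_table()]s).
#' @export
colombia_synthetic_inputs <- function() {
  demo <- synthetic_demography()
  # group-level 2005 percentages; NA = solved from the pooled adult
  # aggregates (overweight 34.2, obese 15.7 over ages 20-59)
  ow <- c(5.0, 12.5, 13.5, 12.6, 18.9, 27.9, 35.5, 38.2, 39.5, 40.0, NA, NA)
  ob <- c(1.5, 3.8, 3.2, 2.8, 5.5, 9.2, 13.71, 17.0, 21.0, 23.0, NA, NA)
  w <- demo$pop[5:12]
  solve_tail <- function(x, target) {
    known <- sum(w[1:6] * x[5:10])
    (target * sum(w) - known) / sum(w[7:8])
  }
  ow[11:12] <- solve_tail(ow, 34.2)
  ob[11:12] <- solve_tail(ob, 15.7)
  P_all <- group_anchor_profile(ow, ob)
  # published per-SES adult (20-59) aggregates in 2005
  adult_ow <- c(lower = 30.7, middle = 34.3, higher = 36.4)
  adult_ob <- c(lower = 13.0, middle = 16.3, higher = 17.2)
  shares <- c(lower = 0.4, middle = 0.2, higher = 0.4)
  prevalence <- list(all = survey_prevalence(2005, P_all, "all"))
  for (s in ses_levels()) {
    Ps <- P_all
    Ps[2, ] <- pmin(P_all[2, ] * adult_ow[[s]] / 34.2, 0.95)
    Ps[3, ] <- pmin(P_all[3, ] * adult_ob[[s]] / 15.7, 0.95)
    Ps[1, ] <- 1 - Ps[2, ] - Ps[3, ]
    prevalence[[s]] <- survey_prevalence(2005, Ps, s)
  }
  list(prevalence = prevalence, demography = demo, shares = shares,
       tr_urban = reference_tr_table("urban"),
       tr_ses = reference_tr_table("ses"))
}
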