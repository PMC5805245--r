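# Synthetic ground truth: transference rates shaped like the published
# estimates, a Colombia-like urban demography, and two survey waves five
# years apart generated by the exact cohort process the estimator assumes.

#' Synthetic urban demography
#'
#' A deterministic demography emulating the urban Colombian population
#' around 2005: group populations of a few million declining with age, a
#' J-shaped mortality schedule, a fertility series declining from about
#' 2.1 to 1.8 children per woman between 2005 and 2030, female fraction
#' 0.523 and birth-category fractions dominated by not-overweight.
#'
#' @param pop_scale Multiplier on the population sizes (default 1).
#' @return A [demography()] object.
#' @export
synthetic_demography <- function(pop_scale = 1) {
  pop <- c(3.10, 3.20, 3.30, 3.10, 2.90, 2.60,
           2.30, 2.20, 2.00, 1.70, 1.40, 1.10) * 1e6 * pop_scale
  mort <- c(0.0040, 0.0004, 0.0005, 0.0012, 0.0016, 0.0016,
            0.0017, 0.0020, 0.0026, 0.0036, 0.0053, 0.0080)
  fert <- data.frame(year = 2005:2030,
                     f = seq(2.1, 1.8, length.out = 26))
  demography(pop, mort, fert)
}

#' Smooth baseline age profile of BMI-category prevalence
#'
#' Logistic-in-age ramps plus a gentle linear trend: overweight rises from
#' about 6% in infancy towards the high 40s late in adulthood (logistic
#' midpoint age 28), obesity from about 1.5% towards roughly 21%
#' (midpoint 36); not-overweight is the complement. The linear component
#' keeps a non-zero age gradient inside every 5-year band: the
#' transference-rate estimator identifies the rates from within-band
#' variation of the cohort columns, so a profile that plateaus would make
#' the per-group inverse problem underdetermined.
#'
#' @param ow_rise,ob_rise Logistic amplitudes of the overweight and obese
#'   ramps (defaults 0.30 and 0.13).
#' @return 3 x 65 prevalence matrix (categories x ages 0..64).
#' @export
baseline_age_profile <- function(ow_rise = 0.34, ob_rise = 0.15) {
  a <- 0:64
  ow <- 0.05 + 0.002 * a + ow_rise / (1 + exp(-(a - 26) / 6))
  ob <- 0.015 + 0.0015 * a + ob_rise / (1 + exp(-(a - 34) / 7))
  P <- rbind(1 - ow - ob, ow, ob)
  dimnames(P) <- list(bmi_categories(), a)
  P
}

draw_truth_rows <- function(profile) {
  # one stratum's 12 rows; relies on the caller for RNG state
  tau1 <- tau2 <- tau3 <- tau4 <- numeric(N_GROUPS)
  if (profile == "paper_like") {
    for (i in 1:N_GROUPS) {
      if (i <= 3) { # childhood groups: recovery flows dominate
        tau1[i] <- stats::runif(1, 0, 0.006)
        tau2[i] <- stats::runif(1, 0, 0.005)
        tau3[i] <- stats::runif(1, 0, 0.04)
        tau4[i] <- stats::runif(1, 0, 0.04)
      } else {
        tau1[i] <- stats::runif(1, 0.005, 0.04)
        tau2[i] <- stats::runif(1, 0.002, 0.017)
        tau3[i] <- stats::runif(1, 0, 1e-6)
        tau4[i] <- stats::runif(1, 0, 1e-6)
      }
    }
  } else { # random_feasible
    tau1 <- stats::runif(N_GROUPS)
    tau2 <- stats::runif(N_GROUPS)
    tau3 <- stats::runif(N_GROUPS)
    tau4 <- stats::runif(N_GROUPS) * (1 - tau2)
  }
  list(tau1 = tau1, tau2 = tau2, tau3 = tau3, tau4 = tau4)
}

#' Generate a synthetic ground-truth scenario
#'
#' Draws a feasible transference-rate table per stratum (the
#' `"paper_like"` profile mirrors the published magnitudes: adult `tau1`
#' in `[0.005, 0.04]`, `tau2` in `[0.002, 0.017]`, near-zero adult
#' recovery rates, recovery flows concentrated in the childhood groups;
#' `"random_feasible"` draws uniformly over the feasible box), together
#' with the synthetic demography and a baseline wave-1 age profile.
#'
#' @param seed Integer RNG seed; the scenario is reproducible under it.
#' @param profile `"paper_like"` (default) or `"random_feasible"`.
#' @param strata Stratum labels (default `"all"`; use [ses_levels()] for a
#'   stratified scenario).
#' @param noise_sd Survey-noise standard deviation on the prevalence scale
#'   (default 0: noiseless waves).
#' @return List of class `"synthetic_scenario"`: `seed`, `profile`,
#'   `truth` ([tr_table()]), `demography`, `baseline` (3 x 65 profile),
#'   `strata`, `noise_sd`.
#' @export
generate_truth <- function(seed, profile = c("paper_like", "random_feasible"),
                           strata = "all", noise_sd = 0) {
  profile <- match.arg(profile)
  truth <- with_seed(seed, {
    parts <- lapply(seq_along(strata), function(k) {
      tv <- draw_truth_rows(profile)
      data.frame(ses = strata[k], age_group = age_group_labels(),
                 tau1 = tv$tau1, tau2 = tv$tau2, tau3 = tv$tau3,
                 tau4 = tv$tau4, stringsAsFactors = FALSE)
    })
    do.call(rbind, parts)
  })
  class(truth) <- c("tr_table", "data.frame")
  validate_tr_table(truth)
  structure(
    list(seed = seed, profile = profile, truth = truth,
         demography = synthetic_demography(),
         baseline = baseline_age_profile(),
         strata = strata, noise_sd = noise_sd),
    class = "synthetic_scenario"
  )
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat("<synthetic_scenario> profile", x$profile, "seed", x$seed,
      "strata", paste(x$strata, collapse = "/"),
      "noise_sd", x$noise_sd, "\n")
  invisible(x)
}

add_survey_noise <- function(P, sd) {
  noisy <- P + matrix(stats::rnorm(length(P), 0, sd), nrow(P))
  clipped <- noisy < 0
  if (any(clipped)) {
    noisy[clipped] <- 0
    message("add_survey_noise: clipped ", sum(clipped),
            " negative prevalence value(s) at 0")
  }
  sweep(noisy, 2, colSums(noisy), "/")
}

#' Generate two synthetic survey waves from a ground-truth scenario
#'
#' Wave 1 (2005) is the baseline age profile. Wave 2 (2010) is generated
#' by the exact cohort process the estimator inverts: for every age `a` in
#' group `i`, the wave-2 prevalence at age `a + 5` is `A_i^5` applied to
#' the wave-1 vector at age `a` (so at zero noise the estimation objective
#' is exactly zero at the true rates); wave-2 ages 0-4 reuse the baseline
#' profile. Optional Gaussian noise is added to both waves and
#' renormalized onto the simplex (negatives clipped at 0, with a message).
#'
#' @param scn A [generate_truth()] scenario.
#' @param noise_sd Override of the scenario's noise level.
#' @param seed Override of the scenario's seed for the noise draws.
#' @return For a single stratum, `list(wave1, wave2)` of
#'   [survey_prevalence()] objects; for several strata, named lists
#'   (`wave1`, `wave2` each a list by stratum).
#' @export
generate_waves <- function(scn, noise_sd = scn$noise_sd, seed = scn$seed) {
  stopifnot(inherits(scn, "synthetic_scenario"))
  make_pair <- function(ses) {
    P1 <- scn$baseline
    P2 <- matrix(NA_real_, 3L, 65L)
    P2[, 1:5] <- scn$baseline[, 1:5]
    taus <- tau_matrix(scn$truth, ses)
    for (i in seq_len(N_GROUPS) - 1L) {
      B <- mat_pow5(build_A(taus[i + 1L, ]))
      P2[, 5L * i + 6:10] <- B %*% P1[, 5L * i + 1:5]
    }
    if (noise_sd > 0) {
      P1 <- add_survey_noise(P1, noise_sd)
      P2 <- add_survey_noise(P2, noise_sd)
    }
    list(wave1 = survey_prevalence(2005, P1, ses),
         wave2 = survey_prevalence(2010, P2, ses))
  }
  with_seed(seed, {
    if (length(scn$strata) == 1L) {
      make_pair(scn$strata)
    } else {
      pairs <- lapply(scn$strata, make_pair)
      names(pairs) <- scn$strata
      list(wave1 = lapply(pairs, `[[`, "wave1"),
           wave2 = lapply(pairs, `[[`, "wave2"))
    }
  })
}
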