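# Shared builders for small, fully-specified model inputs.

# demography with constant fertility and flat mortality, wide year coverage
toy_demography <- function(mortality = rep(0, 12), f = 0, mu = 0.523,
                           theta = c(0.93, 0.05, 0.02),
                           years = 2000:2210) {
  demography(pop = rep(1000, 12), mortality = mortality,
             fertility = data.frame(year = years, f = f),
             mu = mu, theta = theta)
}

# state with every group at the same category split
uniform_state <- function(total_per_group = 1000,
                          split = c(1, 0, 0), year = 2005, ses = "all") {
  stocks <- matrix(rep(total_per_group * split, each = 12), 12, 3)
  population_state(stocks, year = year, ses = ses)
}

zero_tr_table <- function(ses = "all") {
  tr_table(rep(0, 12), rep(0, 12), rep(0, 12), rep(0, 12), ses = ses)
}

# flat prevalence surface across all 65 ages
flat_prevalence <- function(p = c(0.5, 0.3, 0.2), wave = 2005, ses = "all") {
  survey_prevalence(wave, matrix(p, 3, 65), ses)
}

expect_state_equal <- function(a, b, tol = 1e-9) {
  expect_equal(unclass(a), unclass(b), tolerance = tol,
               ignore_attr = TRUE)
}
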