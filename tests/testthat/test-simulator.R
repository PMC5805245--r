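test_that("births split the childbearing population by fertility and theta", {
  # mu=0.5, f=2, childbearing pop 3500 -> 0.5*3500*2/35 = 100 births/yr
  demo <- toy_demography(f = 2, mu = 0.5, theta = c(1, 0, 0))
  stocks <- matrix(0, 12, 3)
  stocks[4:10, 1] <- 500 # ages 15-49 hold 3500 people
  st <- population_state(stocks, 2005)
  B <- births(st, demo, 2005)
  expect_equal(sum(B), 100)
  expect_equal(unname(B), c(100, 0, 0)) # theta = (1,0,0): all not_overweight
  # theta redistributes without changing the total
  demo2 <- toy_demography(f = 2, mu = 0.5, theta = c(0.6, 0.3, 0.1))
  expect_equal(unname(births(st, demo2, 2005)), c(60, 30, 10))
})

test_that("stock-outflow exits are first-order; the literal form stalls", {
  demo <- toy_demography()
  st <- uniform_state(500) # every stock 500 people
  B <- births(st, demo, 2005)
  E <- exit_rates(st, zero_tr_table(), demo, B, "stock_outflow")
  expect_equal(unname(E[, 1]), rep(100, 12)) # 500 / Y=5
  # literal form: zero births and transfers give zero exits regardless of
  # the stock, so the chain never drains
  E_lit <- exit_rates(st, zero_tr_table(), demo, B, "literal_paper")
  expect_equal(max(abs(E_lit)), 0)
  # empty population: no exits either way
  E0 <- exit_rates(uniform_state(0), zero_tr_table(), demo, B)
  expect_equal(max(abs(E0)), 0)
})

test_that("net derivative applies category transfers on top of the chain", {
  demo <- toy_demography()
  tab <- zero_tr_table()
  tab$tau1[6] <- 0.1
  stocks <- matrix(0, 12, 3); stocks[6, 1] <- 100
  st <- population_state(stocks, 2005)
  d <- net_derivative(st, tab, demo, 2005)
  d0 <- net_derivative(st, zero_tr_table(), demo, 2005)
  # transfer component alone: N loses tau1*N = 10/yr, W gains it
  expect_equal(unname((d - d0)[6, ]), c(-10, 10, 0))
  # full derivative includes the group's first-order exit 100/5 = 20
  expect_equal(unname(d[6, ]), c(-30, 10, 0))
  expect_error(net_derivative(population_state(stocks, 2005) - 1,
                              tab, demo, 2005), "negative")
})

test_that("population ledger closes: d(total)/dt = births - deaths - exits", {
  set.seed(11)
  for (rep in 1:20) {
    demo <- toy_demography(mortality = runif(12, 0, 0.02), f = runif(1, 0, 3))
    tab <- tr_table(runif(12, 0, 0.3), runif(12, 0, 0.3),
                    runif(12, 0, 0.3), runif(12, 0, 0.3))
    st <- population_state(matrix(runif(36, 0, 1e5), 12, 3), 2005)
    d <- net_derivative(st, tab, demo, 2005)
    E <- unclass(st) / 5
    expected <- sum(births(st, demo, 2005)) -
      sum(rowSums(E) * (1 - demo$S)) -      # deaths
      sum(E[12, ]) * demo$S[12]             # survivors leaving at 60
    expect_equal(sum(d), expected, tolerance = 1e-6)
  }
})

test_that("one year of integration matches the matrix-exponential oracle", {
  skip_if_not_installed("Matrix")
  demo <- toy_demography(mortality = c(0.01, 0.002, rep(0.001, 10)), f = 0)
  set.seed(3)
  tab <- tr_table(runif(12, 0, 0.2), runif(12, 0, 0.2),
                  runif(12, 0, 0.2), runif(12, 0, 0.2))
  stocks <- matrix(runif(36, 100, 1000), 12, 3)
  st <- population_state(stocks, 2005)
  # independent construction of the linear generator from the stated flows
  M <- matrix(0, 36, 36)
  idx <- function(i, c) (c - 1L) * 12L + i
  for (i in 1:12) {
    t1 <- tab$tau1[i]; t2 <- tab$tau2[i]; t3 <- tab$tau3[i]; t4 <- tab$tau4[i]
    G <- matrix(c(-t1, t1, 0, t4, -(t2 + t4), t2, 0, t3, -t3), 3, 3)
    for (a in 1:3) for (b in 1:3) {
      M[idx(i, a), idx(i, b)] <- M[idx(i, a), idx(i, b)] + G[a, b]
    }
    for (a in 1:3) {
      M[idx(i, a), idx(i, a)] <- M[idx(i, a), idx(i, a)] - 1 / 5
      if (i > 1) M[idx(i, a), idx(i - 1, a)] <- demo$S[i - 1] / 5
    }
  }
  oracle <- as.vector(Matrix::expm(M) %*% as.vector(stocks))
  proj <- run_projection(st, tab, demo, 2005, 2006, dt = 0.01,
                         method = "rk4")
  got <- as.vector(unclass(attr(proj, "final_state")))
  expect_equal(got, oracle, tolerance = 1e-8)
})

test_that("extreme conditions: no fertility, mortality or transfers drains the chain", {
  demo <- toy_demography() # f = 0, mortality 0
  st <- uniform_state(1000, c(0.6, 0.3, 0.1))
  proj <- run_projection(st, zero_tr_table(), demo, 2005, 2030)
  totals <- vapply(2005:2030, function(y) sum(proj$count[proj$year == y]),
                   numeric(1))
  expect_true(all(diff(totals) < 0)) # only the 55-59 exit removes people
  expect_true(all(proj$count >= -1e-9))
  # with zero mortality, the loss equals the integral of the oldest
  # group's maturation outflow only; nobody dies, so category shares of
  # every non-empty group are preserved (transfers are off)
  final <- attr(proj, "final_state")
  expect_equal(unname(state_prevalence(final)[1, ]), c(0.6, 0.3, 0.1),
               tolerance = 1e-9)
})

test_that("integration error is small: halving dt barely moves prevalences", {
  ci <- colombia_synthetic_inputs()
  init <- stocks_from_prevalence(ci$prevalence$all, ci$demography$pop)
  p1 <- run_projection(init, ci$tr_urban, ci$demography, 2005, 2030,
                       dt = 0.25)
  p2 <- run_projection(init, ci$tr_urban, ci$demography, 2005, 2030,
                       dt = 0.125)
  expect_lt(max(abs(p1$prevalence - p2$prevalence)), 1e-3)
})

test_that("euler at fine step agrees with rk4 at coarse step", {
  ci <- colombia_synthetic_inputs()
  init <- stocks_from_prevalence(ci$prevalence$all, ci$demography$pop)
  pe <- run_projection(init, ci$tr_urban, ci$demography, 2005, 2030,
                       dt = 0.01, method = "euler")
  pr <- run_projection(init, ci$tr_urban, ci$demography, 2005, 2030,
                       dt = 0.25, method = "rk4")
  expect_lt(max(abs(pe$prevalence - pr$prevalence)), 1e-3)
})

test_that("dynamics are linear in population scale", {
  ci <- colombia_synthetic_inputs()
  init <- stocks_from_prevalence(ci$prevalence$all, ci$demography$pop)
  p1 <- run_projection(init, ci$tr_urban, ci$demography, 2005, 2015)
  demo_k <- synthetic_demography(pop_scale = 3)
  init_k <- stocks_from_prevalence(ci$prevalence$all, demo_k$pop)
  p3 <- run_projection(init_k, ci$tr_urban, demo_k, 2005, 2015)
  expect_equal(p3$count, 3 * p1$count, tolerance = 1e-9)
  expect_equal(p3$prevalence, p1$prevalence, tolerance = 1e-9)
})

test_that("with no transfers, category shares converge to the birth fractions", {
  theta <- c(0.7, 0.2, 0.1)
  demo <- toy_demography(f = 2.2, theta = theta, years = 2000:2210)
  st <- uniform_state(1000, c(1, 0, 0))
  proj <- run_projection(st, zero_tr_table(), demo, 2000, 2200, dt = 0.25)
  final <- state_prevalence(attr(proj, "final_state"))
  for (i in 1:12) expect_equal(unname(final[i, ]), theta, tolerance = 1e-3)
})

test_that("unknown formulations and bad horizons are rejected", {
  demo <- toy_demography()
  st <- uniform_state(100)
  expect_error(exit_rates(st, zero_tr_table(), demo, c(0, 0, 0), "banana"))
  expect_error(run_projection(st, zero_tr_table(), demo, 2010, 2005))
})
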