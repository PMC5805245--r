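test_that("CSV round trips preserve prevalences, rates and demography", {
  dir <- withr::local_tempdir()
  scn <- generate_truth(5, strata = ses_levels())
  w <- generate_waves(scn)
  p <- file.path(dir, "w1.csv")
  write_prevalence_csv(w$wave1, p)
  back <- read_prevalence_csv(p)
  expect_length(back, 3)
  expect_equal(back[["2005/lower"]]$P, w$wave1$lower$P, tolerance = 1e-4)
  trp <- file.path(dir, "tr.csv")
  write_tr_csv(scn$truth, trp)
  expect_equal(read_tr_csv(trp)$tau1, scn$truth$tau1, tolerance = 1e-4)
  dd <- file.path(dir, "demo")
  write_demography_dir(scn$demography, dd)
  demo2 <- read_demography_dir(dd)
  expect_equal(demo2$pop, scn$demography$pop, tolerance = 1e-4)
  expect_equal(demo2$mu, scn$demography$mu)
  expect_equal(demo2$theta, scn$demography$theta)
  expect_error(read_demography_dir(file.path(dir, "nope")), "missing")
})

test_that("validators flag simplex and range violations with file and rule", {
  dir <- withr::local_tempdir()
  bad_prev <- data.frame(wave = 2005, ses = "all", age_years = c(3, 3, 3),
                         category = bmi_categories(),
                         prevalence = c(0.7, 0.3, 0.2)) # sums to 1.2
  pp <- file.path(dir, "prev.csv")
  write.csv(bad_prev, pp, row.names = FALSE)
  rep1 <- validate_inputs(prevalence = pp)
  expect_false(attr(rep1, "ok"))
  expect_true("simplex" %in% rep1$rule)
  bad_tr <- data.frame(ses = "all", age_group = "0-4", tau1 = -0.2,
                       tau2 = 0.1, tau3 = 0, tau4 = 0)
  tp <- file.path(dir, "tr.csv")
  write.csv(bad_tr, tp, row.names = FALSE)
  rep2 <- validate_inputs(tr = tp)
  expect_true("tau_range" %in% rep2$rule)
  rep3 <- validate_inputs(prevalence = file.path(dir, "ghost.csv"))
  expect_equal(rep3$rule, "exists")
})

test_that("the CLI dispatches, reports usage, and round-trips end to end", {
  expect_equal(suppressMessages(cli_main(character(0))), 2L)
  expect_equal(suppressMessages(cli_main("frobnicate")), 2L)
  dir <- withr::local_tempdir()
  out <- file.path(dir, "fix")
  expect_equal(suppressMessages(
    cli_main(c("synth", "--seed", "3", "--out", out))), 0L)
  expect_true(all(file.exists(file.path(out, c("wave1.csv", "wave2.csv",
                                               "truth_tr.csv")))))
  expect_equal(suppressMessages(
    cli_main(c("validate", "--prevalence", file.path(out, "wave1.csv"),
               "--tr", file.path(out, "truth_tr.csv"),
               "--demography", file.path(out, "demography")))), 0L)
  est <- file.path(dir, "est.csv")
  expect_equal(suppressMessages(
    cli_main(c("estimate", "--wave1", file.path(out, "wave1.csv"),
               "--wave2", file.path(out, "wave2.csv"),
               "--out", est, "--restarts", "8", "--seed", "1"))), 0L)
  tab <- read_tr_csv(est)
  truth <- read_tr_csv(file.path(out, "truth_tr.csv"))
  expect_lt(max(abs(as.matrix(tab[, 3:6]) - as.matrix(truth[, 3:6]))),
            2e-3) # serialization keeps 6 significant digits
  proj <- file.path(dir, "proj.csv")
  expect_equal(suppressMessages(
    cli_main(c("simulate", "--prevalence", file.path(out, "wave1.csv"),
               "--tr", est, "--demography", file.path(out, "demography"),
               "--out", proj, "--t0", "2005", "--t1", "2015"))), 0L)
  got <- read_projection_csv(proj)
  expect_true(all(c(2005, 2015) %in% got$year))
  # per (year, group) prevalences sum to 1
  sums <- tapply(got$prevalence, paste(got$year, got$age_group), sum)
  expect_equal(as.numeric(sums), rep(1, length(sums)), tolerance = 1e-3)
})

test_that("CLI runs are byte-identical under identical config and seed", {
  dir <- withr::local_tempdir()
  for (d in c("a", "b")) {
    suppressMessages(cli_main(c("synth", "--seed", "11", "--noise", "0.005",
                                "--out", file.path(dir, d))))
  }
  for (f in c("wave1.csv", "wave2.csv", "truth_tr.csv")) {
    expect_identical(readLines(file.path(dir, "a", f)),
                     readLines(file.path(dir, "b", f)))
  }
})

test_that("scenario and pr subcommands produce comparable outputs", {
  dir <- withr::local_tempdir()
  fix <- file.path(dir, "fix")
  suppressMessages(cli_main(c("synth", "--seed", "6", "--out", fix)))
  spec <- file.path(dir, "spec.yaml")
  yaml::write_yaml(list(
    label = "school",
    overrides = list(
      list(ages = list("5-9", "10-14"), tau = "tau3", value = 0.02,
           from = 2011, to = 2030),
      list(ages = list("5-9", "10-14"), tau = "tau4", value = 0.02,
           from = 2011, to = 2030)
    )
  ), spec)
  outdir <- file.path(dir, "scen")
  expect_equal(suppressMessages(
    cli_main(c("scenario", "--prevalence", file.path(fix, "wave1.csv"),
               "--tr", file.path(fix, "truth_tr.csv"),
               "--demography", file.path(fix, "demography"),
               "--spec", spec, "--out", outdir,
               "--t0", "2005", "--t1", "2020"))), 0L)
  cmp <- read.csv(file.path(outdir, "comparison.csv"))
  expect_equal(nrow(cmp), 3)
  # pr needs per-stratum projections laid out under <run>/<ses>/
  base <- read_projection_csv(file.path(outdir, "baseline.csv"))
  for (s in c("lower", "higher")) {
    dir.create(file.path(dir, "run", s), recursive = TRUE)
    file.copy(file.path(outdir, "baseline.csv"),
              file.path(dir, "run", s, "projection.csv"))
  }
  prout <- capture.output(
    code <- suppressMessages(cli_main(c("pr", "--run", file.path(dir, "run"),
                                        "--year", "2020"))))
  expect_equal(code, 0L)
  expect_equal(as.numeric(prout), 1, tolerance = 1e-9)
})
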