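# CSV/YAML readers and writers for the package's external interfaces, and
# schema validation of input file sets. Numbers are serialized with 6
# significant digits in scientific notation (e.g. 3.5826E-02).

fmt_sci <- function(x) formatC(x, format = "E", digits = 4)
fmt_full <- function(x) formatC(x, format = "E", digits = 10)

#' Read a long-format prevalence CSV
#'
#' Expected columns: `wave, ses, age_years, category, prevalence` with
#' integer ages 0-64, categories among [bmi_categories()], prevalences in
#' `[0, 1]` summing to 1 per (wave, ses, age).
#'
#' @param path CSV file path.
#' @return Named list of [survey_prevalence()] objects, one per
#'   (wave, ses) pair, names `"<wave>/<ses>"`.
#' @export
read_prevalence_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("wave", "ses", "age_years", "category", "prevalence")
  if (!all(needed %in% names(df))) {
    stop("prevalence CSV must have columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  out <- list()
  for (w in sort(unique(df$wave))) {
    for (s in unique(df$ses[df$wave == w])) {
      sub <- df[df$wave == w & df$ses == s, ]
      P <- matrix(NA_real_, 3L, 65L)
      for (k in seq_len(nrow(sub))) {
        ci <- match(sub$category[k], bmi_categories())
        if (is.na(ci)) stop("unknown category: ", sub$category[k], call. = FALSE)
        a <- sub$age_years[k]
        if (a < 0 || a > 64 || a != round(a)) {
          stop("age_years out of range 0-64: ", a, call. = FALSE)
        }
        P[ci, a + 1L] <- sub$prevalence[k]
      }
      partial <- colSums(is.na(P)) %in% 1:2
      if (any(partial)) {
        stop("ages with incomplete category rows: ",
             paste(which(partial) - 1L, collapse = ", "), call. = FALSE)
      }
      out[[paste0(w, "/", s)]] <- survey_prevalence(w, P, s)
    }
  }
  out
}

#' Write survey prevalences to a long-format CSV
#'
#' @param waves A [survey_prevalence()] or list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_prevalence_csv <- function(waves, path) {
  if (inherits(waves, "survey_prevalence")) waves <- list(waves)
  rows <- lapply(waves, function(w) {
    keep <- colSums(is.na(w$P)) == 0L
    data.frame(
      wave = w$wave, ses = w$ses,
      age_years = rep(0:64, each = 3L)[rep(keep, each = 3L)],
      category = rep(bmi_categories(), 65L)[rep(keep, each = 3L)],
      prevalence = fmt_full(as.vector(w$P[, keep])),
      stringsAsFactors = FALSE
    )
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a transference-rate CSV
#'
#' Expected columns: `ses, age_group, tau1, tau2, tau3, tau4`; scientific
#' notation accepted.
#'
#' @param path CSV file path.
#' @return A [tr_table()].
#' @export
read_tr_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("ses", "age_group", "tau1", "tau2", "tau3", "tau4")
  if (!all(needed %in% names(df))) {
    stop("TR CSV must have columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  out <- df[, needed]
  class(out) <- c("tr_table", "data.frame")
  validate_tr_table(out)
  out
}

#' Write a transference-rate CSV
#'
#' @param x A [tr_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tr_csv <- function(x, path) {
  validate_tr_table(x)
  out <- data.frame(ses = x$ses, age_group = x$age_group,
                    tau1 = fmt_sci(x$tau1), tau2 = fmt_sci(x$tau2),
                    tau3 = fmt_sci(x$tau3), tau4 = fmt_sci(x$tau4),
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a projection CSV
#'
#' Columns `year, ses, age_group, category, count, prevalence`.
#'
#' @param proj A `projection` from [run_projection()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_projection_csv <- function(proj, path) {
  out <- proj
  out$count <- fmt_full(out$count)
  out$prevalence <- fmt_full(out$prevalence)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a projection CSV
#' @param path CSV path written by [write_projection_csv()].
#' @return A `projection`-shaped data frame.
#' @export
read_projection_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("year", "ses", "age_group", "category", "count", "prevalence")
  if (!all(needed %in% names(df))) {
    stop("projection CSV must have columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  class(df) <- c("projection", "data.frame")
  df
}

#' Write a demography to a directory of CSVs plus a config file
#'
#' Writes `population.csv` (`age_group,pop`), `mortality.csv`
#' (`age_group,R`), `fertility.csv` (`year,f`) and `config.yaml` (scalar
#' parameters `mu`, `theta`, `Y`, `YI`, `YF`).
#'
#' @param demo A [demography()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_demography_dir <- function(demo, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(data.frame(age_group = age_group_labels(),
                              pop = fmt_full(demo$pop)),
                   file.path(dir, "population.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(age_group = age_group_labels(),
                              R = fmt_full(demo$mortality)),
                   file.path(dir, "mortality.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(year = demo$fertility$year,
                              f = fmt_full(demo$fertility$f)),
                   file.path(dir, "fertility.csv"),
                   row.names = FALSE, quote = FALSE)
  yaml::write_yaml(list(mu = demo$mu, theta = as.list(demo$theta),
                        Y = demo$Y, YI = demo$YI, YF = demo$YF),
                   file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a demography from a directory written by [write_demography_dir()]
#'
#' @param dir Directory containing `population.csv`, `mortality.csv`,
#'   `fertility.csv` and `config.yaml`.
#' @return A [demography()].
#' @export
read_demography_dir <- function(dir) {
  need <- file.path(dir, c("population.csv", "mortality.csv",
                           "fertility.csv", "config.yaml"))
  missing <- need[!file.exists(need)]
  if (length(missing)) {
    stop("missing demography file(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  pop <- utils::read.csv(need[1], stringsAsFactors = FALSE)
  mort <- utils::read.csv(need[2], stringsAsFactors = FALSE)
  fert <- utils::read.csv(need[3], stringsAsFactors = FALSE)
  cfg <- yaml::read_yaml(need[4])
  ord <- match(age_group_labels(), pop$age_group)
  if (anyNA(ord)) stop("population.csv must cover all 12 age groups",
                       call. = FALSE)
  demography(pop$pop[ord],
             mort$R[match(age_group_labels(), mort$age_group)],
             fert,
             mu = cfg$mu, theta = unlist(cfg$theta),
             Y = cfg$Y %||% 5, YI = cfg$YI %||% 15, YF = cfg$YF %||% 49)
}

#' Read a scenario specification from a YAML file
#'
#' Layout: a `label` and an `overrides` list of
#' `{ages: [...], tau: tau3, value: 0.02, from: 2011, to: 2030}` entries
#' (`ages` uses age-group labels).
#'
#' @param path YAML file path.
#' @return A [scenario_spec()].
#' @export
read_scenario_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  overrides <- lapply(cfg$overrides, function(ov) {
    list(age_groups = unlist(ov$ages), tau = ov$tau, value = ov$value,
         from = ov$from, to = ov$to)
  })
  scenario_spec(overrides, label = cfg$label %||% "scenario")
}

validation_row <- function(file, row, rule, message) {
  data.frame(file = file, row = row, rule = rule, message = message,
             stringsAsFactors = FALSE)
}

#' Validate a set of input files
#'
#' Schema-checks any subset of the package's input files: a prevalence
#' CSV (columns, category labels, age range, per-age simplex sums), a
#' transference-rate CSV (rate ranges, joint overweight-exit constraint)
#' and a demography directory (file completeness, non-negative rates).
#' Every violation is reported with file, row and rule.
#'
#' @param prevalence,tr,demography Optional paths (demography is a
#'   directory).
#' @return Data frame with columns `file, row, rule, message` (zero rows
#'   when everything passes) and attribute `ok`.
#' @export
validate_inputs <- function(prevalence = NULL, tr = NULL, demography = NULL) {
  report <- validation_row(character(0), integer(0), character(0),
                           character(0))
  add <- function(...) report <<- rbind(report, validation_row(...))
  if (!is.null(prevalence)) {
    if (!file.exists(prevalence)) {
      add(prevalence, NA_integer_, "exists", "file not found")
    } else {
      df <- tryCatch(utils::read.csv(prevalence, stringsAsFactors = FALSE),
                     error = function(e) NULL)
      needed <- c("wave", "ses", "age_years", "category", "prevalence")
      if (is.null(df) || !all(needed %in% names(df))) {
        add(prevalence, NA_integer_, "columns",
            paste("required columns:", paste(needed, collapse = ", ")))
      } else {
        bad_cat <- which(!df$category %in% bmi_categories())
        for (r in bad_cat) add(prevalence, r, "category",
                               paste("unknown category", df$category[r]))
        bad_age <- which(df$age_years < 0 | df$age_years > 64)
        for (r in bad_age) add(prevalence, r, "age_range",
                               paste("age outside 0-64:", df$age_years[r]))
        bad_p <- which(df$prevalence < 0 | df$prevalence > 1)
        for (r in bad_p) add(prevalence, r, "prevalence_range",
                             paste("prevalence outside [0,1]:",
                                   df$prevalence[r]))
        if (!length(bad_cat) && !length(bad_age) && !length(bad_p)) {
          sums <- stats::aggregate(prevalence ~ wave + ses + age_years,
                                   df, sum)
          off <- which(abs(sums$prevalence - 1) > 1e-6)
          for (r in off) {
            add(prevalence, NA_integer_, "simplex",
                sprintf("wave %s ses %s age %d: prevalences sum to %.6f",
                        sums$wave[r], sums$ses[r], sums$age_years[r],
                        sums$prevalence[r]))
          }
        }
      }
    }
  }
  if (!is.null(tr)) {
    if (!file.exists(tr)) {
      add(tr, NA_integer_, "exists", "file not found")
    } else {
      df <- tryCatch(utils::read.csv(tr, stringsAsFactors = FALSE),
                     error = function(e) NULL)
      needed <- c("ses", "age_group", "tau1", "tau2", "tau3", "tau4")
      if (is.null(df) || !all(needed %in% names(df))) {
        add(tr, NA_integer_, "columns",
            paste("required columns:", paste(needed, collapse = ", ")))
      } else {
        taus <- as.matrix(df[, c("tau1", "tau2", "tau3", "tau4")])
        for (r in which(rowSums(taus < 0 | taus > 1) > 0)) {
          add(tr, r, "tau_range", "rate outside [0, 1]")
        }
        for (r in which(df$tau2 + df$tau4 > 1 + 1e-9)) {
          add(tr, r, "tau_joint", "tau2 + tau4 > 1")
        }
      }
    }
  }
  if (!is.null(demography)) {
    res <- tryCatch({ read_demography_dir(demography); NULL },
                    error = function(e) conditionMessage(e))
    if (!is.null(res)) add(demography, NA_integer_, "demography", res)
  }
  attr(report, "ok") <- nrow(report) == 0L
  report
}
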