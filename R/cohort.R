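#' Describe one cohort of a synthetic study design
#'
#' @param name cohort id.
#' @param n_individuals number of individuals.
#' @param age_range length-2 numeric, years.
#' @param n_timepoints scans per individual (> 1 makes the cohort longitudinal).
#' @param infant logical; infant cohorts follow the sleep/wake rule (scans at
#'   age <= 3 y are labelled `sleep`).
#' @return a one-row tibble usable as a row of a design table.
#' @export
cohort_spec <- function(name, n_individuals, age_range, n_timepoints = 1,
                        infant = FALSE) {
  stopifnot(n_individuals >= 1, length(age_range) == 2, age_range[1] > 0,
            age_range[2] > age_range[1], n_timepoints >= 1)
  tibble::tibble(name = name, n_individuals = n_individuals,
                 age_lo = age_range[1], age_hi = age_range[2],
                 n_timepoints = as.integer(n_timepoints), infant = infant)
}

#' Default three-cohort lifespan design
#'
#' One longitudinal infant cohort (two timepoints per individual), one
#' developmental cohort and one adult cohort, 320 scans in total; a
#' desk-scale stand-in for a multi-cohort lifespan study. Adjacent cohorts
#' overlap in age: cohort mean offsets are only identifiable from ages where
#' cohorts share support, the same requirement batch-harmonization methods
#' place on site covariate distributions.
#'
#' @return a design tibble for [sample_cohort()].
#' @export
default_cohort_design <- function() {
  dplyr::bind_rows(
    cohort_spec("infant", 60, c(0.1, 5), n_timepoints = 2, infant = TRUE),
    cohort_spec("dev", 100, c(3, 25)),
    cohort_spec("adult", 100, c(18, 100)))
}

#' Sample a scan-level cohort table from a design
#'
#' Ages are drawn uniformly on the square-root-age scale within each cohort's
#' range (denser sampling early in life, as lifespan studies are designed).
#' Longitudinal cohorts add per-individual follow-up scans at increasing ages.
#' Infant-cohort scans at age <= 3 y are labelled `arousal = "sleep"`, the
#' rest `"wake"`.
#'
#' @param design a design tibble built from [cohort_spec()] rows.
#' @param seed integer seed.
#' @return a `CohortTable` tibble: `scan_id`, `individual_id`, `cohort_id`,
#'   `age_years`, `sex`, `arousal`.
#' @export
#' @examples
#' cohort <- sample_cohort(default_cohort_design(), seed = 1)
#' dplyr::count(cohort, cohort_id, arousal)
sample_cohort <- function(design, seed = 1) {
  if (is.null(design) || nrow(design) == 0) stop_param("empty cohort design")
  req <- c("name", "n_individuals", "age_lo", "age_hi", "n_timepoints", "infant")
  if (!all(req %in% names(design)))
    stop_param("design lacks columns: %s", paste(setdiff(req, names(design)), collapse = ", "))
  set.seed(seed)
  rows <- purrr::pmap(design, function(name, n_individuals, age_lo, age_hi,
                                       n_timepoints, infant) {
    ind <- sprintf("%s_%03d", name, seq_len(n_individuals))
    base <- sqrt(age_lo) + (sqrt(age_hi) - sqrt(age_lo)) * runif(n_individuals)
    ages <- (base^2)
    out <- list()
    for (tp in seq_len(n_timepoints)) {
      a <- if (tp == 1) ages else pmin(age_hi, ages + (tp - 1) * runif(n_individuals, 0.5, 1.5))
      out[[tp]] <- tibble::tibble(
        individual_id = ind, cohort_id = name, age_years = a,
        timepoint = tp)
    }
    dplyr::bind_rows(out) |>
      dplyr::mutate(infant = infant)
  })
  tbl <- dplyr::bind_rows(rows)
  n <- nrow(tbl)
  tbl |>
    dplyr::mutate(
      sex = sample(c("M", "F"), n, replace = TRUE),
      arousal = dplyr::if_else(.data$infant & .data$age_years <= 3, "sleep", "wake"),
      scan_id = sprintf("scan_%04d", dplyr::row_number())) |>
    dplyr::select("scan_id", "individual_id", "cohort_id", "age_years",
                  "sex", "arousal")
}

#' Split an infant cohort into sleep/wake sub-cohorts
#'
#' Arousal state confounds infant scans: scans acquired during natural sleep
#' (age <= 3 y in the infant cohort) form their own stratum before trajectory
#' fitting. Returns the table with a `cohort_strat` factor combining cohort
#' and arousal for infant scans.
#'
#' @param cohort a `CohortTable` tibble.
#' @return the table with an added `cohort_strat` column.
#' @export
split_arousal_cohort <- function(cohort) {
  stopifnot(all(c("cohort_id", "arousal") %in% names(cohort)))
  dplyr::mutate(cohort, cohort_strat = dplyr::if_else(
    .data$arousal == "sleep",
    paste0(.data$cohort_id, "_sleep"), .data$cohort_id))
}
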