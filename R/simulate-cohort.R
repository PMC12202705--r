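# Synthetic tumor-free survival cohorts under single-hit kinetics.

#' Specify a synthetic tumor-watch cohort
#'
#' Describes a cohort of animals observed for tumor appearance under the
#' single-hit model: each subject initiates a tumor after an exponential
#' waiting time with rate \eqn{\lambda = \ln 2 / t_{1/2}}, tumors become
#' detectable only after a fixed lag, and observation stops at a fixed
#' follow-up time (administrative right-censoring).
#'
#' @param n_subjects number of animals in the cohort.
#' @param half_time_weeks initiation half-time \eqn{t_{1/2}} in weeks — the
#'   time after the lag by which half the cohort is expected to have a
#'   detectable tumor.
#' @param lag_weeks detection lag \eqn{t_0} in weeks: tumors initiated at
#'   time zero still need this long to reach detectable size. Default 4.
#' @param followup_weeks administrative censoring time in weeks; must exceed
#'   `lag_weeks`. Default 104 (a two-year observation window).
#' @param seed integer RNG seed; the generated table is a pure function of
#'   the spec including this seed.
#' @param group label recorded in the output table (e.g. a genotype).
#' @return an object of class `cohort_spec`.
#' @seealso [simulate_incidence_cohort()]
#' @export
cohort_spec <- function(n_subjects, half_time_weeks, lag_weeks = 4,
                        followup_weeks = 104, seed = 1L,
                        group = "cohort") {
  n_subjects <- check_scalar(n_subjects, "n_subjects", lower = 1,
                             integer = TRUE)
  half_time_weeks <- check_scalar(half_time_weeks, "half_time_weeks",
                                  lower = 0, lower_open = TRUE)
  lag_weeks <- check_scalar(lag_weeks, "lag_weeks", lower = 0)
  followup_weeks <- check_scalar(followup_weeks, "followup_weeks",
                                 lower = 0, lower_open = TRUE)
  if (followup_weeks < lag_weeks) {
    stop("'followup_weeks' must be at least 'lag_weeks'", call. = FALSE)
  }
  seed <- check_scalar(seed, "seed", integer = TRUE)
  stopifnot(is.character(group), length(group) == 1L)
  structure(
    list(n_subjects = n_subjects, half_time_weeks = half_time_weeks,
         lag_weeks = lag_weeks, followup_weeks = followup_weeks,
         seed = seed, group = group),
    class = "cohort_spec"
  )
}

#' Simulate a tumor-free survival table under single-hit kinetics
#'
#' Draws one latent initiation time per subject as
#' `lag + Exponential(rate = log(2) / half_time)`, records an event if the
#' tumor becomes detectable within follow-up, and censors at the follow-up
#' time otherwise. The returned truth record keeps the uncensored latent
#' times, so every downstream estimate can be recomputed exactly.
#'
#' @param spec a [cohort_spec()].
#' @return a list of class `cohort_sim` with elements
#'   \describe{
#'     \item{table}{data frame with columns `subject_id`, `group`,
#'       `time_weeks`, `event` (1 = tumor detected, 0 = censored).}
#'     \item{truth}{list with the latent (uncensored) detection times and
#'       the generating spec.}
#'   }
#' @examples
#' sim <- simulate_incidence_cohort(
#'   cohort_spec(200, half_time_weeks = 33, lag_weeks = 4,
#'               followup_weeks = 60, seed = 1)
#' )
#' mean(sim$table$event)
#' @export
simulate_incidence_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_subjects
  lambda <- log(2) / spec$half_time_weeks
  latent <- with_seed(spec$seed, spec$lag_weeks + stats::rexp(n, rate = lambda))
  event <- as.integer(latent <= spec$followup_weeks)
  tab <- data.frame(
    subject_id = sprintf("s%04d", seq_len(n)),
    group = spec$group,
    time_weeks = pmin(latent, spec$followup_weeks),
    event = event,
    stringsAsFactors = FALSE
  )
  structure(
    list(table = tab,
         truth = list(latent_times = latent, spec = spec)),
    class = "cohort_sim"
  )
}

#' Write / read a tumor-free survival table
#'
#' The on-disk schema is a plain CSV with columns
#' `subject_id,group,time_weeks,event`.
#'
#' @param table a survival data frame (as produced by
#'   [simulate_incidence_cohort()]).
#' @param path file path.
#' @return `write_survival_csv` returns `path` invisibly;
#'   `read_survival_csv` returns the validated data frame.
#' @export
write_survival_csv <- function(table, path) {
  stopifnot(all(c("subject_id", "group", "time_weeks", "event") %in%
                  names(table)))
  utils::write.csv(
    table[, c("subject_id", "group", "time_weeks", "event")],
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' @rdname write_survival_csv
#' @export
read_survival_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "time_weeks", "event")
  if (!all(need %in% names(tab))) {
    stop("survival CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(tab$time_weeks < 0)) stop("negative times in survival table",
                                    call. = FALSE)
  if (!all(tab$event %in% c(0L, 1L))) stop("'event' must be 0 or 1",
                                           call. = FALSE)
  tab
}
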