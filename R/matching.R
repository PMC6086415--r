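#' Risk-set sample matched controls for each case
#'
#' Incidence-density (risk-set) sampling: for each case with follow-up time
#' t = index - entry, eligible controls are cohort members of the same sex
#' and month/year of cohort entry whose age at entry is within one year of
#' the case's, and who are still at risk at their own entry + t (in the
#' cohort, alive, and MI-free at that date). Up to \code{ratio} controls are
#' drawn by simple random sampling without replacement; each control's
#' assigned index date is its own entry + t, giving exactly the case's
#' follow-up time. Future cases may serve as controls before their events,
#' and a person may appear in several sets. Sets with fewer than
#' \code{ratio} (but at least one) eligible controls are retained; cases
#' with no eligible control are dropped and logged.
#'
#' @param cohort Cohort data frame from [assemble_cohort()].
#' @param ratio Maximum number of controls per case.
#' @param age_caliper Maximum |case age - control age| at entry, in years.
#' @param seed Optional integer seed making the sampling reproducible.
#' @return Data frame with columns \code{set_id}, \code{person_id},
#'   \code{index_date}, \code{case} (1 for the case row, 0 for controls),
#'   ordered by set; attribute \code{"dropped"} records cases without
#'   eligible controls.
#' @export
sample_controls <- function(cohort, ratio = 10, age_caliper = 1,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  cs <- cohort[cohort$exit_reason == "outcome", , drop = FALSE]
  cs <- cs[order(cs$exit_date, cs$person_id), , drop = FALSE]
  key <- paste(cohort$sex, .month_year(cohort$entry_date))
  pool <- split(seq_len(nrow(cohort)), key)
  ckey <- paste(cs$sex, .month_year(cs$entry_date))

  out <- vector("list", nrow(cs))
  dropped <- character(0)
  entry_i <- .as_day(cohort$entry_date)
  exit_i <- .as_day(cohort$exit_date)
  is_case_exit <- cohort$exit_reason == "outcome"
  for (s in seq_len(nrow(cs))) {
    t_fu <- .as_day(cs$exit_date[s]) - .as_day(cs$entry_date[s])
    cand <- pool[[ckey[s]]]
    cand <- cand[cohort$person_id[cand] != cs$person_id[s]]
    if (length(cand)) {
      assigned <- entry_i[cand] + t_fu
      ok <- abs(cohort$age_at_entry[cand] - cs$age_at_entry[s]) <=
        age_caliper &
        (exit_i[cand] > assigned |
           (exit_i[cand] == assigned & !is_case_exit[cand]))
      cand <- cand[ok]
    }
    if (!length(cand)) { dropped <- c(dropped, cs$person_id[s]); next }
    take <- if (length(cand) > ratio)
      sample(cand, ratio) else cand[sample.int(length(cand))]
    out[[s]] <- data.frame(
      set_id = s,
      person_id = c(cs$person_id[s], cohort$person_id[take]),
      index_date = .restore_day(c(.as_day(cs$exit_date[s]),
                                  entry_i[take] + t_fu),
                                cohort$entry_date),
      case = c(1L, rep(0L, length(take))))
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res))
    res <- data.frame(set_id = integer(), person_id = character(),
                      index_date = as.Date(integer(), origin = "1970-01-01"),
                      case = integer())
  rownames(res) <- NULL
  structure(res, dropped = dropped)
}
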