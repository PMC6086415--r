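#' Assemble the new-user NSAID cohort
#'
#' Applies the new-user entry rules: cohort entry is the first dispensing of
#' a single study NSAID at or after the study start, for persons aged at
#' least \code{min_age} completed years at entry, with at least one year of
#' data history before entry and no study-NSAID dispensing during the
#' one-year washout. Aspirin does not count as NSAID use. Exit is the
#' earliest of the first qualifying acute-MI admission on/after entry,
#' death, end of coverage, and study end. Every excluded person is returned
#' with a machine-readable exclusion reason.
#'
#' @param persons Data frame \code{person_id}, \code{birth_date}, \code{sex},
#'   \code{coverage_start}, \code{coverage_end}, \code{death_date} (NA when
#'   alive).
#' @param dispensings Dispensing table (all persons).
#' @param hospital_episodes Hospitalization table, used to ascertain the MI
#'   outcome via [ascertain_mi()].
#' @param study_start,study_end Study calendar window (Dates).
#' @param min_age Minimum age in completed years at entry.
#' @param washout_days Length of the NSAID-free baseline (days).
#' @param min_history_days Minimum data history before entry (days).
#' @param pci_prefixes Passed to [ascertain_mi()].
#' @return List with \code{cohort} (data frame \code{person_id},
#'   \code{entry_date}, \code{exit_date}, \code{exit_reason},
#'   \code{age_at_entry}, \code{sex}) and \code{exclusions} (data frame
#'   \code{person_id}, \code{reason}); together they partition
#'   \code{persons}.
#' @export
assemble_cohort <- function(persons, dispensings, hospital_episodes,
                            study_start, study_end, min_age = 66,
                            washout_days = 365, min_history_days = 365,
                            pci_prefixes = "480") {
  .assert_columns(persons, c("person_id", "birth_date", "sex",
                             "coverage_start", "coverage_end"), "persons")
  .assert_columns(dispensings, c("person_id", "drug", "dispense_date"),
                  "dispensings")
  if (study_start >= study_end)
    .stopf("study_start must precede study_end")
  mi_all <- ascertain_mi(hospital_episodes, pci_prefixes = pci_prefixes,
                         all = TRUE)

  nd <- dispensings[.is_nsaid(dispensings$drug), c("person_id", "drug",
                                                   "dispense_date")]
  nd <- nd[order(nd$person_id, nd$dispense_date), ]
  nd_by <- split(seq_len(nrow(nd)), nd$person_id)
  mi_by <- split(mi_all$index_date, mi_all$person_id)

  n <- nrow(persons)
  entry <- rep(as.Date(NA), n); exit <- rep(as.Date(NA), n)
  reason <- rep(NA_character_, n); exit_reason <- rep(NA_character_, n)
  age <- rep(NA_integer_, n)

  for (i in seq_len(n)) {
    pid <- persons$person_id[i]
    rows <- nd_by[[as.character(pid)]]
    if (is.null(rows)) { reason[i] <- "no_nsaid_dispensing"; next }
    dts <- nd$dispense_date[rows]
    cand <- rows[dts >= study_start & dts <= study_end]
    if (!length(cand)) { reason[i] <- "no_nsaid_dispensing"; next }
    e <- nd$dispense_date[cand[1L]]
    same_day <- nd$drug[cand][nd$dispense_date[cand] == e]
    if (length(unique(same_day)) > 1L) { reason[i] <- "multiple_nsaids"; next }
    a <- .completed_years(persons$birth_date[i], e)
    if (a < min_age) { reason[i] <- "age"; next }
    if (persons$coverage_start[i] > e - min_history_days) {
      reason[i] <- "insufficient_history"; next
    }
    washout <- dts >= e - washout_days & dts < e
    if (any(washout)) { reason[i] <- "baseline_use"; next }

    mi_dates <- mi_by[[as.character(pid)]]
    first_mi <- if (!is.null(mi_dates) && any(mi_dates >= e))
      min(mi_dates[mi_dates >= e]) else as.Date(NA)
    cand_exit <- c(outcome = as.integer(first_mi),
                   death = as.integer(persons$death_date[i] %||% NA),
                   coverage_end = as.integer(persons$coverage_end[i]),
                   study_end = as.integer(study_end))
    x <- min(cand_exit, na.rm = TRUE)
    if (x < as.integer(e)) { reason[i] <- "exit_before_entry"; next }
    # tie priority follows the order above (outcome first)
    why <- names(cand_exit)[which(!is.na(cand_exit) & cand_exit == x)[1L]]
    entry[i] <- e; exit[i] <- as.Date(x, origin = "1970-01-01")
    exit_reason[i] <- why; age[i] <- a
  }

  inc <- !is.na(entry)
  list(cohort = data.frame(person_id = persons$person_id[inc],
                           entry_date = entry[inc], exit_date = exit[inc],
                           exit_reason = exit_reason[inc],
                           age_at_entry = age[inc],
                           sex = persons$sex[inc]),
       exclusions = data.frame(person_id = persons$person_id[!inc],
                               reason = reason[!inc]))
}
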