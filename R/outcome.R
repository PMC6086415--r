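## Acute MI outcome ascertainment from hospital discharge abstracts.
## Hospitalization tables store the ordered diagnosis list and the procedure
## list as ";"-separated strings (position = rank in the list).

.split_codes <- function(x) {
  if (!length(x)) return(list())
  x <- as.character(x)
  x[is.na(x)] <- ""
  strsplit(x, ";", fixed = TRUE)
}

.validate_icd <- function(codes_list, what) {
  pat <- "^[EV]?[0-9]{2,3}(\\.[0-9]{1,2})?$"
  bad <- vapply(codes_list,
                function(cc) length(cc) > 0 && any(!grepl(pat, cc)),
                logical(1))
  if (any(bad))
    .stopf("malformed %s code string(s) in row(s): %s", what,
           paste(utils::head(which(bad), 10), collapse = ", "))
  invisible(codes_list)
}

.has_prefix <- function(codes_list, prefixes, leading_only = FALSE) {
  vapply(codes_list, function(cc) {
    if (!length(cc)) return(FALSE)
    if (leading_only) cc <- cc[1L]
    any(outer(cc, prefixes, startsWith))
  }, logical(1))
}

#' Ascertain hospitalizations for acute myocardial infarction
#'
#' An episode qualifies as an acute MI when any discharge diagnosis carries
#' ICD-9 prefix 410 and either the length of stay is at least
#' \code{min_stay} days, or the patient was transferred to/from another
#' institution, or a percutaneous coronary intervention procedure code is
#' present. Length of stay is discharge minus admission with the admission
#' day counted as day 0.
#'
#' @param hospital_episodes Data frame with columns \code{person_id},
#'   \code{admission_date}, \code{discharge_date}, \code{diagnoses},
#'   \code{procedures}, \code{transfer_flag}.
#' @param pci_prefixes Procedure-code prefixes exempting short stays
#'   (default the percutaneous coronary intervention family, prefix 480).
#' @param min_stay Minimum qualifying stay in days absent transfer/PCI.
#' @param all If \code{TRUE} return every qualifying admission; otherwise the
#'   earliest per person.
#' @return Data frame \code{person_id}, \code{index_date} (first qualifying
#'   admission date), or all qualifying admissions when \code{all = TRUE}.
#' @export
ascertain_mi <- function(hospital_episodes, pci_prefixes = "480",
                         min_stay = 3, all = FALSE) {
  h <- hospital_episodes
  if (!nrow(h))
    return(data.frame(person_id = character(), index_date = as.Date(integer(),
                                                  origin = "1970-01-01")))
  .assert_columns(h, c("person_id", "admission_date", "discharge_date",
                       "diagnoses", "transfer_flag"), "hospital_episodes")
  dx <- .validate_icd(.split_codes(h$diagnoses), "diagnosis")
  pr <- .split_codes(h$procedures %||% rep("", nrow(h)))
  is_mi <- .has_prefix(dx, "410")
  stay <- .as_day(h$discharge_date) - .as_day(h$admission_date)
  rescue <- (h$transfer_flag %in% TRUE) | .has_prefix(pr, pci_prefixes)
  qual <- is_mi & (stay >= min_stay | rescue)
  out <- data.frame(person_id = h$person_id[qual],
                    index_date = h$admission_date[qual])
  out <- out[order(out$person_id, out$index_date), , drop = FALSE]
  if (!all)
    out <- out[!duplicated(out$person_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
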