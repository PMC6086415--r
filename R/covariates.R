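## Confounder ascertainment. Comorbidities are recognised through two routes:
## ICD-9 hospital discharge diagnoses and dispensed marker drugs (claims for
## drug classes that reflect an ambulatory diagnosis). Marker-drug claims use
## drug names "marker_<class>".

#' Default comorbidity definitions
#'
#' Each comorbidity maps to ICD-9 diagnosis-code prefixes and marker drug
#' classes, with its ascertainment window: \code{"before_index"} (first
#' occurrence any time before the index date), \code{"before_entry"}
#' (mediators on the causal pathway -- hypertension, congestive heart
#' failure, renal failure -- are assessed only before cohort entry), or
#' \code{"mixed_365"} (diagnoses any time before index, marker drugs only in
#' the 365 days before index: COPD and GI ulcer disease, whose drug markers
#' are unspecific). The marker-drug class lists are configurable stand-ins;
#' the diagnosis prefixes follow the usual ICD-9 groupings.
#'
#' @return Named list of definitions, one per comorbidity indicator.
#' @export
comorbidity_definitions <- function() {
  list(
    diabetes = list(dx = "250", drugs = "antidiabetic",
                    window = "before_index"),
    hyperlipidemia = list(dx = "272", drugs = "statin",
                          window = "before_index"),
    hypertension = list(dx = c("401", "402", "403", "404", "405"),
                        drugs = "antihypertensive", window = "before_entry"),
    previous_mi = list(dx = "410", drugs = character(),
                       window = "before_index"),
    chd = list(dx = c("411", "412", "413", "414"), drugs = "antianginal",
               window = "before_index"),
    chf = list(dx = "428", drugs = "chf_drug", window = "before_entry"),
    cerebrovascular = list(dx = c("430", "431", "432", "433", "434", "435",
                                  "436", "437", "438"),
                           drugs = character(), window = "before_index"),
    pvd = list(dx = c("440", "441", "442", "443"), drugs = character(),
               window = "before_index"),
    copd = list(dx = c("490", "491", "492", "493", "494", "495", "496"),
                drugs = "respiratory_drug", window = "mixed_365"),
    gi_ulcer = list(dx = c("531", "532", "533", "534"), drugs = "gi_drug",
                    window = "mixed_365"),
    gi_bleed = list(dx = "578", drugs = character(),
                    window = "before_index"),
    renal_failure = list(dx = c("584", "585", "586"), drugs = character(),
                         window = "before_entry"),
    rheumatoid_arthritis = list(dx = "714", drugs = "dmard",
                                window = "before_index")
  )
}

#' Ascertain the confounder vector at an index date
#'
#' Applies the window rules: by default a comorbidity is present when its
#' first diagnosis or marker-drug claim predates the index date; mediating
#' comorbidities (hypertension, CHF, renal failure) are assessed only before
#' cohort entry; COPD/GI-ulcer marker drugs count only in the 365 days
#' before index; oral corticosteroids, clopidogrel, and cardioprotective
#' aspirin are ascertained over the 30 days preceding the index date.
#' Coronary heart disease has a broad definition (any-position 411-414
#' diagnosis, PCI/CABG procedure, or anti-anginal marker drugs) and a strict
#' sensitivity definition (leading-position 411/413/414 diagnosis, a 480/481
#' procedure, or the marker-drug algorithm firing within the 30 days before
#' index); the strict definition implies the broad one.
#'
#' @param person One row of the persons table.
#' @param dispensings,hospital_episodes This person's claims.
#' @param index_date,entry_date Index and cohort-entry dates.
#' @param chd_definition \code{"broad"} or \code{"strict"}.
#' @param defs Comorbidity definitions, see [comorbidity_definitions()].
#' @return One-row data frame: \code{age_at_index}, one logical column per
#'   comorbidity, plus \code{corticosteroids_30d}, \code{clopidogrel_30d},
#'   \code{aspirin_30d}.
#' @export
ascertain_covariates <- function(person, dispensings, hospital_episodes,
                                 index_date, entry_date,
                                 chd_definition = c("broad", "strict"),
                                 defs = comorbidity_definitions()) {
  chd_definition <- match.arg(chd_definition)
  idx <- .as_day(index_date); ent <- .as_day(entry_date)
  h <- hospital_episodes
  dx_list <- .split_codes(h$diagnoses)
  pr_list <- .split_codes(h$procedures %||% rep("", nrow(h)))
  adm <- .as_day(h$admission_date)
  drug <- sub("^marker_", "", as.character(dispensings$drug))
  ddate <- .as_day(dispensings$dispense_date)

  has_dx <- function(prefixes, lo, hi, leading = FALSE) {
    if (!length(adm)) return(FALSE)
    in_win <- adm >= lo & adm < hi
    any(in_win & .has_prefix(dx_list, prefixes, leading_only = leading))
  }
  has_proc <- function(prefixes, hi) {
    if (!length(adm)) return(FALSE)
    any(adm < hi & .has_prefix(pr_list, prefixes))
  }
  has_drug <- function(classes, lo, hi) {
    if (!length(classes) || !length(ddate)) return(FALSE)
    any(drug %in% classes & ddate >= lo & ddate < hi)
  }

  out <- list(age_at_index = .completed_years(person$birth_date,
                                              .restore_day(idx, index_date)))
  for (nm in names(defs)) {
    d <- defs[[nm]]
    out[[nm]] <- switch(d$window,
      before_entry = has_dx(d$dx, -Inf, ent) || has_drug(d$drugs, -Inf, ent),
      mixed_365 = has_dx(d$dx, -Inf, idx) ||
        has_drug(d$drugs, idx - 365L, idx),
      has_dx(d$dx, -Inf, idx) || has_drug(d$drugs, -Inf, idx))
  }
  if (chd_definition == "strict") {
    out$chd <- has_dx(c("411", "413", "414"), -Inf, idx, leading = TRUE) ||
      has_proc(c("480", "481"), idx) ||
      has_drug(defs$chd$drugs, idx - 30L, idx)
  } else {
    out$chd <- out$chd || has_proc(c("480", "481"), idx)
  }
  out$corticosteroids_30d <- has_drug("corticosteroid", idx - 30L, idx)
  out$clopidogrel_30d <- has_drug("clopidogrel", idx - 30L, idx)
  out$aspirin_30d <- classify_aspirin(
    dispensings[dispensings$drug == "aspirin", , drop = FALSE],
    .restore_day(idx, index_date))
  as.data.frame(out)
}
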