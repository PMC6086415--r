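## Synthetic claims generator. Emulates an elderly insured population with a
## one-year drug-free baseline, outpatient NSAID/aspirin/marker-drug
## dispensing streams (refill gaps, dose changes, switches, intermittent
## use), comorbidities encoded through both hospital diagnoses and marker
## drugs, and acute-MI admissions drawn from a per-day Bernoulli event model
## whose odds are multiplicative in configured odds ratios except where a
## configured interaction structure overrides the joint drug-by-profile
## multiplier, so the ground-truth RERI is known analytically.

.dx_codes <- list(
  diabetes = "250.0", hyperlipidemia = "272.4", hypertension = "401.9",
  previous_mi = "410.9", chd = "414.0", chf = "428.0",
  cerebrovascular = "434.9", pvd = "443.9", copd = "496",
  gi_ulcer = "533.9", gi_bleed = "578.9", renal_failure = "585",
  rheumatoid_arthritis = "714.0")

#' Simulation configuration for the synthetic claims generator
#'
#' Collects and validates every knob of the generator. Defaults describe an
#' elderly claims population: comorbidity prevalences follow the magnitudes
#' reported for elderly NSAID users, marginal NSAID odds ratios sit in the
#' 1.2-1.6 range typical for acute MI, and the event model is a per-day
#' Bernoulli with baseline odds of about 1% per year.
#'
#' @param n_persons Number of persons.
#' @param study_start,study_end Study calendar window.
#' @param age_range Age range (years) at study start; the lower default of
#'   60 deliberately admits persons below the cohort's 66-year rule so the
#'   age filter is exercised.
#' @param p_male Probability of male sex.
#' @param coverage_start_range Offset range (days, relative to study start)
#'   for the start of insurance coverage; positive offsets create persons
#'   with insufficient history.
#' @param annual_death_prob Annual probability of (non-MI) death.
#' @param nsaid_spell_rate Expected NSAID treatment spells per person-year.
#' @param refills_mean Mean number of additional refills per spell.
#' @param days_supplied Days supplied per fill.
#' @param intermittent_prob Probability that a refill gap is a long
#'   (episode-breaking) pause, drawn uniformly from
#'   \code{intermittent_gap_range}, rather than a 0-2 day gap.
#' @param intermittent_gap_range Day range of episode-breaking refill gaps.
#' @param dose_change_prob Per-refill probability of switching dose.
#' @param switch_prob Per-refill probability of switching to another NSAID
#'   while the current supply may still be running.
#' @param market_shares Named probabilities over the six NSAID groups.
#' @param dose_menus Named list per common NSAID: \code{doses} (mg/day) and
#'   \code{probs}.
#' @param aspirin_user_prob Baseline probability of being an aspirin user;
#'   \code{aspirin_cv_extra} is added for persons with CHD or previous MI
#'   (confounding by indication).
#' @param aspirin_cv_extra See \code{aspirin_user_prob}.
#' @param aspirin_doses,aspirin_dose_probs Aspirin daily-dose menu.
#' @param comorbidity_prevalence Named prevalences.
#' @param or_comorbidity Named marginal odds ratios per comorbidity.
#' @param or_nsaid Named marginal odds ratios per NSAID group (at the
#'   reference dose under the dose effect model).
#' @param or_aspirin Odds ratio for current aspirin exposure.
#' @param baseline_daily_odds Baseline odds of MI per person-day.
#' @param effect_model \code{"binary"} (the NSAID odds ratio applies on
#'   exposed days) or \code{"dose"} (log odds scale linearly with daily dose
#'   relative to \code{dose_ref}).
#' @param dose_ref Named reference daily dose per common NSAID.
#' @param effect_window_days Days past supply end during which the drug
#'   still carries risk.
#' @param interactions List of interaction specifications, each
#'   \code{list(nsaid =, profile =, structure = "exactly_additive" |
#'   "exactly_multiplicative" | "custom", or11 =)}; on days of joint
#'   exposure the combined drug-profile odds multiplier is exactly the
#'   implied OR11.
#' @param short_stay_frac Fraction of MI admissions with stays under 3 days.
#' @param short_stay_rescue Probability such a short stay carries a
#'   transfer flag or PCI procedure (and hence still qualifies).
#' @param dx_route_prob,drug_route_prob Probabilities that a comorbidity is
#'   encoded through a hospitalization diagnosis and through marker-drug
#'   dispensings (both routes may fire).
#' @param seed Integer seed; all generator randomness derives from it.
#' @return Validated list of class \code{"sim_config"}.
#' @export
sim_config <- function(n_persons = 2000,
                       study_start = as.Date("1993-01-01"),
                       study_end = as.Date("2004-09-30"),
                       age_range = c(60, 90), p_male = 0.5,
                       coverage_start_range = c(-1095L, 365L),
                       annual_death_prob = 0.03,
                       nsaid_spell_rate = 0.4, refills_mean = 2,
                       days_supplied = 30, intermittent_prob = 0.15,
                       intermittent_gap_range = c(10L, 90L),
                       dose_change_prob = 0.15, switch_prob = 0.1,
                       market_shares = c(celecoxib = 0.25,
                                         diclofenac = 0.15,
                                         ibuprofen = 0.10, naproxen = 0.20,
                                         rofecoxib = 0.20,
                                         other_nsaid = 0.10),
                       dose_menus = list(
                         celecoxib = list(doses = c(100, 200, 400),
                                          probs = c(0.25, 0.55, 0.20)),
                         diclofenac = list(doses = c(75, 100, 150),
                                           probs = c(0.25, 0.25, 0.50)),
                         ibuprofen = list(doses = c(600, 1200, 2400),
                                          probs = c(0.3, 0.5, 0.2)),
                         naproxen = list(doses = c(500, 750, 1000),
                                         probs = c(0.3, 0.5, 0.2)),
                         rofecoxib = list(doses = c(12.5, 25, 50),
                                          probs = c(0.25, 0.6, 0.15)),
                         other_nsaid = list(doses = 100, probs = 1)),
                       aspirin_user_prob = 0.18, aspirin_cv_extra = 0.25,
                       aspirin_doses = c(80, 325, 650),
                       aspirin_dose_probs = c(0.70, 0.25, 0.05),
                       comorbidity_prevalence = c(
                         diabetes = 0.16, hyperlipidemia = 0.30,
                         hypertension = 0.42, previous_mi = 0.065,
                         chd = 0.30, chf = 0.07, cerebrovascular = 0.09,
                         pvd = 0.06, copd = 0.22, gi_ulcer = 0.28,
                         gi_bleed = 0.023, renal_failure = 0.015,
                         rheumatoid_arthritis = 0.016),
                       or_comorbidity = c(
                         diabetes = 2.0, hyperlipidemia = 1.4,
                         hypertension = 1.4, previous_mi = 2.6, chd = 2.6,
                         chf = 2.2, cerebrovascular = 2.0, pvd = 2.8,
                         copd = 1.6, gi_ulcer = 1.5, gi_bleed = 1.6,
                         renal_failure = 2.7, rheumatoid_arthritis = 1.4),
                       or_nsaid = c(celecoxib = 1.2, diclofenac = 1.6,
                                    ibuprofen = 1.4, naproxen = 1.4,
                                    rofecoxib = 1.5, other_nsaid = 1.3),
                       or_aspirin = 1.0,
                       baseline_daily_odds = 3e-5,
                       effect_model = c("binary", "dose"),
                       dose_ref = c(celecoxib = 200, diclofenac = 150,
                                    ibuprofen = 1200, naproxen = 750,
                                    rofecoxib = 25, other_nsaid = 100),
                       effect_window_days = 0,
                       interactions = list(),
                       short_stay_frac = 0.15, short_stay_rescue = 0.6,
                       dx_route_prob = 0.7, drug_route_prob = 0.8,
                       seed = 1L) {
  cfg <- as.list(environment())
  cfg$effect_model <- match.arg(effect_model)
  chk_prob <- function(x, nm) {
    if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
      .stopf("invalid config field `%s`: probabilities must be in [0, 1]",
             nm)
  }
  chk_or <- function(x, nm) {
    if (any(!is.finite(x)) || any(x <= 0))
      .stopf("invalid config field `%s`: odds ratios must be positive", nm)
  }
  if (!is.numeric(n_persons) || n_persons < 0)
    .stopf("invalid config field `n_persons`: must be >= 0")
  if (!(study_start < study_end))
    .stopf("invalid config field `study_start`: must precede `study_end`")
  for (nm in c("p_male", "intermittent_prob", "dose_change_prob",
               "switch_prob", "aspirin_user_prob", "aspirin_cv_extra",
               "comorbidity_prevalence", "short_stay_frac",
               "short_stay_rescue", "dx_route_prob", "drug_route_prob",
               "annual_death_prob", "baseline_daily_odds"))
    chk_prob(cfg[[nm]], nm)
  for (nm in c("or_comorbidity", "or_nsaid", "or_aspirin")) chk_or(cfg[[nm]], nm)
  for (ia in cfg$interactions) {
    if (!ia$nsaid %in% nsaid_groups() && ia$nsaid != "aspirin")
      .stopf("invalid config field `interactions`: unknown nsaid `%s`",
             ia$nsaid)
    if (!ia$profile %in% names(cfg$comorbidity_prevalence) &&
        ia$profile != "aspirin")
      .stopf("invalid config field `interactions`: unknown profile `%s`",
             ia$profile)
    if (identical(ia$structure, "custom")) {
      if (is.null(ia$or11) || !is.finite(ia$or11) || ia$or11 <= 0)
        .stopf("invalid config field `interactions`: custom or11 must be > 0")
    } else if (!ia$structure %in% c("exactly_additive",
                                    "exactly_multiplicative"))
      .stopf("invalid config field `interactions`: unknown structure `%s`",
             ia$structure)
  }
  structure(cfg, class = "sim_config")
}

#' Implied joint odds ratio under an interaction structure
#'
#' Exactly additive joint effects give OR11 = OR10 + OR01 - 1 (RERI = 0);
#' exactly multiplicative joint effects give OR11 = OR10 x OR01 (product
#' coefficient 0); a custom structure returns the supplied OR11.
#'
#' @param or10,or01 Marginal odds ratios.
#' @param structure One of \code{"exactly_additive"},
#'   \code{"exactly_multiplicative"}, \code{"custom"}.
#' @param or11 Joint OR for the custom structure.
#' @return Implied OR11.
#' @export
implied_or11 <- function(or10, or01,
                         structure = c("exactly_additive",
                                       "exactly_multiplicative", "custom"),
                         or11 = NULL) {
  switch(match.arg(structure),
         exactly_additive = or10 + or01 - 1,
         exactly_multiplicative = or10 * or01,
         custom = {
           if (is.null(or11)) .stopf("custom structure requires `or11`")
           or11
         })
}

.sample1 <- function(x, prob = NULL) x[sample.int(length(x), 1L,
                                                  prob = prob)]

#' Generate a synthetic claims population
#'
#' Draws persons, outpatient dispensings (NSAIDs, aspirin, marker drugs)
#' and comorbidity hospitalizations according to the configuration. MI
#' outcomes are added separately by [simulate_outcomes()]. Output is
#' byte-identical for a fixed config (all randomness flows from
#' \code{config$seed}, with one sub-stream per table).
#'
#' @param config A [sim_config()].
#' @return List of class \code{"claims_population"} with \code{persons},
#'   \code{dispensings}, \code{hospitalizations}, \code{comorbidities}
#'   (ground-truth indicator/onset table) and \code{config}.
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- as.integer(config$n_persons)
  s0 <- .as_day(config$study_start); s1 <- .as_day(config$study_end)
  empty <- function() list(
    persons = data.frame(person_id = character(), birth_date = as.Date(
      integer(), origin = "1970-01-01"), sex = character(),
      coverage_start = as.Date(integer(), origin = "1970-01-01"),
      coverage_end = as.Date(integer(), origin = "1970-01-01"),
      death_date = as.Date(integer(), origin = "1970-01-01")),
    dispensings = data.frame(person_id = character(), drug = character(),
                             dispense_date = as.Date(integer(),
                                                     origin = "1970-01-01"),
                             strength = numeric(), quantity = numeric(),
                             days_supplied = integer()),
    hospitalizations = data.frame(person_id = character(),
                                  admission_date = as.Date(integer(),
                                                    origin = "1970-01-01"),
                                  discharge_date = as.Date(integer(),
                                                    origin = "1970-01-01"),
                                  diagnoses = character(),
                                  procedures = character(),
                                  transfer_flag = logical()),
    comorbidities = data.frame(person_id = character()))
  if (n == 0L)
    return(structure(c(empty(), list(config = config)),
                     class = "claims_population"))

  ## persons ----------------------------------------------------------------
  set.seed(config$seed)
  pid <- sprintf("P%06d", seq_len(n))
  sex <- ifelse(stats::runif(n) < config$p_male, "M", "F")
  age0 <- stats::runif(n, config$age_range[1], config$age_range[2])
  birth <- s0 - as.integer(round(age0 * 365.25)) - sample(0:364, n, TRUE)
  cov_start <- s0 + sample(config$coverage_start_range[1]:
                             config$coverage_start_range[2], n, TRUE)
  death_rate <- -log(1 - config$annual_death_prob) / 365
  death_off <- if (death_rate > 0)
    as.integer(round(stats::rexp(n, death_rate))) else rep(200000L, n)
  death <- cov_start + pmax(death_off, 30L)
  admin_end <- rep(s1 + 90L, n)
  early <- stats::runif(n) < 0.1
  admin_end[early] <- cov_start[early] +
    as.integer(stats::runif(sum(early)) * (s1 - cov_start[early]))
  cov_end <- pmin(admin_end, death)
  has_death <- death <= admin_end & death <= s1 + 90L
  persons <- data.frame(
    person_id = pid,
    birth_date = .restore_day(birth, config$study_start),
    sex = sex,
    coverage_start = .restore_day(cov_start, config$study_start),
    coverage_end = .restore_day(cov_end, config$study_start),
    death_date = .restore_day(ifelse(has_death, death, NA_integer_),
                              config$study_start))

  ## comorbidities (ground truth + encodings) -------------------------------
  set.seed(config$seed + 1L)
  com_names <- names(config$comorbidity_prevalence)
  com <- data.frame(person_id = pid)
  onset <- data.frame(person_id = pid)
  hosp <- list(); hk <- 0L
  marker_cls <- list(diabetes = "antidiabetic", hyperlipidemia = "statin",
                     hypertension = "antihypertensive", chd = "antianginal",
                     chf = "chf_drug", copd = "respiratory_drug",
                     gi_ulcer = "gi_drug", rheumatoid_arthritis = "dmard")
  marker <- list(); mk <- 0L
  filler_dx <- c("V70.0", "780.9", "729.5")
  for (cm in com_names) {
    present <- stats::runif(n) < config$comorbidity_prevalence[[cm]]
    com[[cm]] <- present
    on <- rep(NA_integer_, n)
    idx <- which(present)
    if (length(idx)) {
      if (cm == "previous_mi") {
        hi <- pmin(cov_end[idx], s0)
        lo <- cov_start[idx]
        bad <- hi < lo; hi[bad] <- lo[bad]
      } else {
        lo <- cov_start[idx]; hi <- cov_end[idx]
      }
      on[idx] <- lo + as.integer(stats::runif(length(idx)) * (hi - lo + 1))
      dx_route <- stats::runif(length(idx)) < config$dx_route_prob |
        cm == "previous_mi"
      for (j in seq_along(idx)) {
        i <- idx[j]
        if (dx_route[j]) {
          stay <- if (cm == "previous_mi") .sample1(3:10) else .sample1(2:10)
          lead <- stats::runif(1) < 0.6 || cm == "previous_mi"
          dxs <- if (lead) c(.dx_codes[[cm]], .sample1(filler_dx))
          else c(.sample1(filler_dx), .dx_codes[[cm]])
          hk <- hk + 1L
          hosp[[hk]] <- list(person_id = pid[i], admission = on[i],
                             discharge = on[i] + stay,
                             diagnoses = paste(dxs, collapse = ";"),
                             procedures = "", transfer = FALSE)
        }
        cls <- marker_cls[[cm]]
        if (!is.null(cls) && stats::runif(1) < config$drug_route_prob) {
          nf <- 1L + stats::rpois(1, 3)
          dates <- on[i] + cumsum(c(.sample1(0:30),
                                    sample(20:90, nf - 1, replace = TRUE)))
          dates <- dates[dates <= cov_end[i]]
          for (d in dates) {
            mk <- mk + 1L
            marker[[mk]] <- list(person_id = pid[i],
                                 drug = paste0("marker_", cls),
                                 date = d)
          }
        }
      }
    }
    onset[[cm]] <- on
  }
  # concomitant treatment markers (corticosteroids, clopidogrel)
  for (cc in list(c("corticosteroid", 0.04), c("clopidogrel", 0.03))) {
    users <- which(stats::runif(n) < as.numeric(cc[2]))
    for (i in users) {
      nf <- 1L + stats::rpois(1, 4)
      dates <- cov_start[i] +
        sort(as.integer(stats::runif(nf) * pmax(cov_end[i] - cov_start[i], 1)))
      for (d in dates) {
        mk <- mk + 1L
        marker[[mk]] <- list(person_id = pid[i],
                             drug = paste0("marker_", cc[1]), date = d)
      }
    }
  }

  ## NSAID + aspirin dispensings --------------------------------------------
  set.seed(config$seed + 2L)
  disp <- list(); dk <- 0L
  add_fill <- function(i, drug, date, dose, ds) {
    dk <<- dk + 1L
    disp[[dk]] <<- list(person_id = pid[i], drug = drug, date = date,
                        strength = dose, quantity = ds, days_supplied = ds)
  }
  drugs6 <- names(config$market_shares)
  ds <- as.integer(config$days_supplied)
  for (i in seq_len(n)) {
    # NSAID treatment initiation: spells begin at a person-specific first-use
    # date and recur at the spell rate thereafter (new-user pattern)
    span_all <- max(cov_end[i] - cov_start[i], 1)
    first_use <- cov_start[i] + as.integer(stats::runif(1) * span_all)
    span_years <- max(cov_end[i] - first_use, 0) / 365.25
    n_spells <- 1L + stats::rpois(1, config$nsaid_spell_rate * span_years)
    if (stats::runif(1) < 0.25) n_spells <- 0L   # never-users
    if (n_spells > 0) {
      starts <- c(first_use, first_use +
                    sort(as.integer(stats::runif(n_spells - 1L) *
                                      max(cov_end[i] - first_use - 30, 1))))
      for (st in starts) {
        drug <- .sample1(drugs6, config$market_shares)
        menu <- config$dose_menus[[drug]]
        dose <- .sample1(menu$doses, menu$probs)
        n_ref <- 1L + stats::rpois(1, config$refills_mean)
        date <- st
        for (r in seq_len(n_ref)) {
          if (date > cov_end[i]) break
          add_fill(i, drug, date, dose, ds)
          if (stats::runif(1) < config$switch_prob) {
            drug <- .sample1(setdiff(drugs6, drug))
            menu <- config$dose_menus[[drug]]
            dose <- .sample1(menu$doses, menu$probs)
            date <- date + .sample1(5:ds)     # switch mid-supply
            next
          }
          if (stats::runif(1) < config$dose_change_prob)
            dose <- .sample1(menu$doses, menu$probs)
          gap <- if (stats::runif(1) < config$intermittent_prob)
            .sample1(config$intermittent_gap_range[1]:
                       config$intermittent_gap_range[2]) else
            .sample1(0:2, c(0.7, 0.2, 0.1))
          date <- date + ds + gap
        }
      }
    }
    # aspirin: chronic users, 7-day grace exercised by gaps of 0-12 days
    p_asp <- config$aspirin_user_prob +
      config$aspirin_cv_extra * (isTRUE(com$chd[i]) ||
                                   isTRUE(com$previous_mi[i]))
    if (stats::runif(1) < p_asp) {
      adose <- .sample1(config$aspirin_doses, config$aspirin_dose_probs)
      date <- cov_start[i] +
        as.integer(stats::runif(1) * pmax(cov_end[i] - cov_start[i], 1))
      while (date <= cov_end[i]) {
        add_fill(i, "aspirin", date, adose, ds)
        date <- date + ds + .sample1(0:12, c(30, rep(6, 7), rep(1, 5)))
      }
    }
  }

  bindl <- function(lst, fields, dates) {
    if (!length(lst)) return(NULL)
    out <- lapply(fields, function(f) unlist(lapply(lst, `[[`, f),
                                             use.names = FALSE))
    names(out) <- fields
    for (f in dates) out[[f]] <- .restore_day(out[[f]], config$study_start)
    as.data.frame(out)
  }
  d1 <- bindl(disp, c("person_id", "drug", "date", "strength", "quantity",
                      "days_supplied"), "date")
  d2 <- bindl(marker, c("person_id", "drug", "date"), "date")
  if (!is.null(d2)) {
    d2$strength <- 10; d2$quantity <- 30; d2$days_supplied <- 30L
  }
  dispensings <- rbind(
    if (!is.null(d1)) stats::setNames(d1, c("person_id", "drug",
                                            "dispense_date", "strength",
                                            "quantity", "days_supplied")),
    if (!is.null(d2)) stats::setNames(d2[c("person_id", "drug", "date",
                                           "strength", "quantity",
                                           "days_supplied")],
                                      c("person_id", "drug",
                                        "dispense_date", "strength",
                                        "quantity", "days_supplied")))
  if (is.null(dispensings)) dispensings <- empty()$dispensings
  dispensings <- dispensings[order(dispensings$person_id,
                                   dispensings$dispense_date,
                                   dispensings$drug), ]
  rownames(dispensings) <- NULL
  # no same-day fills of two distinct study NSAIDs: keep the first
  nsaid_rows <- which(.is_nsaid(dispensings$drug))
  key_n <- paste(dispensings$person_id[nsaid_rows],
                 dispensings$dispense_date[nsaid_rows])
  drop_rows <- nsaid_rows[duplicated(key_n)]
  if (length(drop_rows))
    dispensings <- dispensings[-drop_rows, , drop = FALSE]

  hospitalizations <- bindl(hosp, c("person_id", "admission", "discharge",
                                    "diagnoses", "procedures", "transfer"),
                            c("admission", "discharge"))
  if (is.null(hospitalizations)) hospitalizations <- empty()$hospitalizations
  else names(hospitalizations) <- c("person_id", "admission_date",
                                    "discharge_date", "diagnoses",
                                    "procedures", "transfer_flag")
  hospitalizations <- hospitalizations[order(hospitalizations$person_id,
                                             hospitalizations$admission_date), ]
  rownames(hospitalizations) <- NULL
  for (cm in com_names)
    onset[[cm]] <- .restore_day(onset[[cm]], config$study_start)
  comorbidities <- com
  attr(comorbidities, "onset") <- onset

  structure(list(persons = persons, dispensings = dispensings,
                 hospitalizations = hospitalizations,
                 comorbidities = comorbidities, config = config),
            class = "claims_population")
}

#' @export
print.claims_population <- function(x, ...) {
  cat("Synthetic claims population:", nrow(x$persons), "persons,",
      nrow(x$dispensings), "dispensings,", nrow(x$hospitalizations),
      "hospital episodes\n")
  invisible(x)
}

#' Simulate acute-MI outcomes and append their hospitalizations
#'
#' Runs the per-day Bernoulli event model over each person's coverage
#' within the study window: daily MI odds equal the baseline odds times the
#' odds ratios of that day's current drug exposures (from the episode
#' construction rules, optionally dose-scaled and extended by
#' \code{effect_window_days}) and of the comorbidities present, with
#' configured interaction pairs overriding the joint drug-profile
#' multiplier by the implied OR11. Only the first event per person is
#' kept. The admission receives a 410.x diagnosis in leading position and a
#' length of stay of at least 3 days except for a configured fraction of
#' short stays, of which a configured share carries a transfer flag or PCI
#' procedure code.
#'
#' @param population A [generate_population()] result.
#' @return The population with MI admissions appended to
#'   \code{hospitalizations}; ground-truth event days are kept in attribute
#'   \code{"mi_truth"}.
#' @export
simulate_outcomes <- function(population) {
  stopifnot(inherits(population, "claims_population"))
  config <- population$config
  set.seed(config$seed + 3L)
  persons <- population$persons
  n <- nrow(persons)
  if (n == 0L) return(population)
  s0 <- .as_day(config$study_start); s1 <- .as_day(config$study_end)
  cov_start <- .as_day(persons$coverage_start)
  cov_end <- .as_day(persons$coverage_end)
  onset <- attr(population$comorbidities, "onset")
  com_names <- names(config$comorbidity_prevalence)
  log_base <- log(config$baseline_daily_odds)
  disp <- population$dispensings
  disp_by <- split(seq_len(nrow(disp)), disp$person_id)
  dv_drug <- as.character(disp$drug)
  dv_date <- .as_day(disp$dispense_date)
  dv_dose <- disp$strength * disp$quantity / disp$days_supplied
  dv_ds <- as.integer(disp$days_supplied)
  ref <- config$dose_ref
  w_eff <- as.integer(config$effect_window_days)

  ia_list <- lapply(config$interactions, function(ia) {
    or10 <- if (ia$nsaid == "aspirin") config$or_aspirin
    else config$or_nsaid[[ia$nsaid]]
    or01 <- if (ia$profile == "aspirin") config$or_aspirin
    else config$or_comorbidity[[ia$profile]]
    ia$or11 <- implied_or11(or10, or01, ia$structure, ia$or11)
    ia$or10 <- or10; ia$or01 <- or01
    ia
  })

  mi <- list(); mcount <- 0L
  mi_codes <- c("410.0", "410.1", "410.2", "410.4", "410.7", "410.9")
  for (i in seq_len(n)) {
    lo <- max(cov_start[i], s0); hi <- min(cov_end[i], s1)
    if (hi < lo) next
    nd <- hi - lo + 1L
    lp <- rep(log_base, nd)
    com_active <- list()
    for (cm in com_names) {
      if (!isTRUE(population$comorbidities[[cm]][i])) next
      on <- .as_day(onset[[cm]][i])
      from <- max(on - lo + 1L, 1L)
      if (from > nd) next
      lp[from:nd] <- lp[from:nd] + log(config$or_comorbidity[[cm]])
      com_active[[cm]] <- from
    }
    rows <- disp_by[[persons$person_id[i]]]
    drug_lp <- NULL; drug_on <- NULL; asp_on <- NULL
    if (!is.null(rows)) {
      eps <- .episodes_core(dv_drug[rows], dv_date[rows], dv_dose[rows],
                            dv_ds[rows])
      if (length(eps$drug)) {
        e_start <- eps$start; e_end <- eps$end
        drug_lp <- numeric(nd)
        drug_on <- vector("list", 0)
        for (k in seq_along(eps$drug)) {
          dg <- eps$drug[k]
          a <- max(e_start[k] - lo + 1L, 1L)
          b <- min(e_end[k] + (if (dg == "aspirin") 0L else w_eff) - lo + 1L,
                   nd)
          if (b < a) next
          if (dg == "aspirin") {
            if (eps$dose[k] >= 40 && eps$dose[k] <= 650) {
              if (is.null(asp_on)) asp_on <- logical(nd)
              asp_on[a:b] <- TRUE
            }
          } else {
            eff <- if (config$effect_model == "dose")
              log(config$or_nsaid[[dg]]) * eps$dose[k] / ref[[dg]]
            else log(config$or_nsaid[[dg]])
            if (is.null(drug_on[[dg]])) drug_on[[dg]] <- logical(nd)
            # overwrite, never stack: recompute exposure day by day
            seg <- a:b
            drug_lp[seg] <- eff
            drug_on[[dg]][seg] <- TRUE
          }
        }
      }
    }
    if (!is.null(asp_on)) lp[asp_on] <- lp[asp_on] + log(config$or_aspirin)
    if (!is.null(drug_lp)) lp <- lp + drug_lp
    for (ia in ia_list) {
      d_ind <- if (ia$nsaid == "aspirin") asp_on else drug_on[[ia$nsaid]]
      if (is.null(d_ind)) next
      p_from <- if (ia$profile == "aspirin") {
        if (is.null(asp_on)) next else NULL
      } else com_active[[ia$profile]]
      p_ind <- if (ia$profile == "aspirin") asp_on else {
        if (is.null(p_from)) next
        v <- logical(nd); v[p_from:nd] <- TRUE; v
      }
      joint <- d_ind & p_ind
      if (!any(joint)) next
      # joint multiplier becomes exactly or11 (drug contribution on joint
      # days is the drug's marginal log OR under the binary model; under
      # the dose model the override is defined at the reference dose)
      lp[joint] <- lp[joint] + log(ia$or11) - log(ia$or10) - log(ia$or01)
    }
    p <- stats::plogis(lp)
    u <- stats::runif(nd)
    ev <- which(u < p)
    if (!length(ev)) next
    day <- lo + ev[1L] - 1L
    short <- stats::runif(1) < config$short_stay_frac
    stay <- if (short) .sample1(1:2) else .sample1(3:14)
    transfer <- FALSE; proc <- ""
    if (short && stats::runif(1) < config$short_stay_rescue) {
      if (stats::runif(1) < 0.5) transfer <- TRUE else proc <- "480.1"
    }
    mcount <- mcount + 1L
    mi[[mcount]] <- list(person_id = persons$person_id[i], admission = day,
                         discharge = day + stay,
                         diagnoses = .sample1(mi_codes),
                         procedures = proc, transfer = transfer)
  }
  if (mcount) {
    mi_df <- data.frame(
      person_id = vapply(mi, `[[`, character(1), "person_id"),
      admission_date = .restore_day(vapply(mi, `[[`, numeric(1),
                                           "admission"),
                                    config$study_start),
      discharge_date = .restore_day(vapply(mi, `[[`, numeric(1),
                                           "discharge"),
                                    config$study_start),
      diagnoses = vapply(mi, `[[`, character(1), "diagnoses"),
      procedures = vapply(mi, `[[`, character(1), "procedures"),
      transfer_flag = vapply(mi, `[[`, logical(1), "transfer"))
    population$hospitalizations <- rbind(population$hospitalizations, mi_df)
    population$hospitalizations <- population$hospitalizations[
      order(population$hospitalizations$person_id,
            population$hospitalizations$admission_date), ]
    rownames(population$hospitalizations) <- NULL
    attr(population$hospitalizations, "mi_truth") <- mi_df
  }
  population
}

#' Write a claims population as delimited tables with a JSON sidecar
#'
#' Writes persons.csv, dispensings.csv, hospitalizations.csv (ISO-8601
#' dates) and ground_truth.json (the configuration, including implied
#' interaction OR11 values).
#'
#' @param population A [generate_population()] (optionally after
#'   [simulate_outcomes()]) result.
#' @param dir Output directory, created if needed.
#' @return \code{dir}, invisibly.
#' @export
write_claims <- function(population, dir) {
  stopifnot(inherits(population, "claims_population"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(population$persons, file.path(dir, "persons.csv"),
                   row.names = FALSE)
  utils::write.csv(population$dispensings,
                   file.path(dir, "dispensings.csv"), row.names = FALSE)
  utils::write.csv(population$hospitalizations,
                   file.path(dir, "hospitalizations.csv"),
                   row.names = FALSE)
  cfg <- unclass(population$config)
  cfg$interactions <- lapply(cfg$interactions, function(ia) {
    or10 <- if (ia$nsaid == "aspirin") cfg$or_aspirin
    else cfg$or_nsaid[[ia$nsaid]]
    or01 <- if (ia$profile == "aspirin") cfg$or_aspirin
    else cfg$or_comorbidity[[ia$profile]]
    ia$implied_or11 <- implied_or11(or10, or01, ia$structure, ia$or11)
    ia$true_reri <- ia$implied_or11 - or10 - or01 + 1
    ia
  })
  cfg$study_start <- format(cfg$study_start)
  cfg$study_end <- format(cfg$study_end)
  jsonlite::write_json(cfg, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a claims population written by [write_claims()]
#'
#' @param dir Directory containing the three tables.
#' @return List with persons, dispensings, hospitalizations (dates parsed).
#' @export
read_claims <- function(dir) {
  rd <- function(f, dates) {
    x <- utils::read.csv(file.path(dir, f), stringsAsFactors = FALSE)
    for (d in dates) x[[d]] <- as.Date(x[[d]])
    x
  }
  list(persons = rd("persons.csv", c("birth_date", "coverage_start",
                                     "coverage_end", "death_date")),
       dispensings = rd("dispensings.csv", "dispense_date"),
       hospitalizations = rd("hospitalizations.csv",
                             c("admission_date", "discharge_date")))
}
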