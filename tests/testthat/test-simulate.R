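test_that("configuration validation names the offending field", {
  expect_error(sim_config(comorbidity_prevalence = c(diabetes = 1.3)),
               "comorbidity_prevalence")
  expect_error(sim_config(or_nsaid = c(celecoxib = -1)), "or_nsaid")
  expect_error(sim_config(study_start = as.Date("2005-01-01"),
                          study_end = as.Date("1993-01-01")),
               "study_start")
  expect_error(sim_config(n_persons = -5), "n_persons")
  expect_error(sim_config(interactions = list(
    list(nsaid = "celecoxib", profile = "chd", structure = "custom",
         or11 = -2))), "or11")
  expect_error(sim_config(interactions = list(
    list(nsaid = "quinine", profile = "chd",
         structure = "exactly_additive"))), "nsaid")
})

test_that("implied joint odds ratios follow the interaction structure", {
  expect_equal(implied_or11(2, 3, "exactly_additive"), 4)
  expect_equal(implied_or11(2, 3, "exactly_multiplicative"), 6)
  expect_equal(implied_or11(2, 3, "custom", or11 = 5.5), 5.5)
})

test_that("zero persons gives three empty collections", {
  pop <- generate_population(sim_config(n_persons = 0))
  expect_equal(nrow(pop$persons), 0L)
  expect_equal(nrow(pop$dispensings), 0L)
  expect_equal(nrow(pop$hospitalizations), 0L)
})

test_that("generation is byte-identical under a fixed seed", {
  cfg <- sim_config(n_persons = 120, study_end = as.Date("1995-12-31"),
                    baseline_daily_odds = 5e-4, seed = 42)
  p1 <- simulate_outcomes(generate_population(cfg))
  p2 <- simulate_outcomes(generate_population(cfg))
  expect_identical(p1$persons, p2$persons)
  expect_identical(p1$dispensings, p2$dispensings)
  expect_identical(p1$hospitalizations, p2$hospitalizations)
  p3 <- generate_population(sim_config(n_persons = 120,
                                       study_end = as.Date("1995-12-31"),
                                       baseline_daily_odds = 5e-4,
                                       seed = 43))
  expect_false(identical(p1$dispensings, p3$dispensings))
})

test_that("zero switch probability and one drug give single-drug streams", {
  cfg <- sim_config(n_persons = 60, study_end = as.Date("1995-12-31"),
                    switch_prob = 0,
                    market_shares = c(celecoxib = 1, diclofenac = 0,
                                      ibuprofen = 0, naproxen = 0,
                                      rofecoxib = 0, other_nsaid = 0),
                    seed = 9)
  pop <- generate_population(cfg)
  nsaids <- pop$dispensings$drug[pop$dispensings$drug %in% nsaid_groups()]
  expect_true(all(nsaids == "celecoxib"))
})

test_that("dispensing dates stay inside coverage windows", {
  cfg <- sim_config(n_persons = 150, study_end = as.Date("1996-12-31"),
                    seed = 14)
  pop <- generate_population(cfg)
  m <- match(pop$dispensings$person_id, pop$persons$person_id)
  expect_true(all(pop$dispensings$dispense_date >=
                    pop$persons$coverage_start[m]))
  expect_true(all(pop$dispensings$dispense_date <=
                    pop$persons$coverage_end[m]))
})

test_that("claims tables round-trip through CSV with a JSON sidecar", {
  cfg <- sim_config(n_persons = 40, study_end = as.Date("1994-12-31"),
                    interactions = list(list(nsaid = "celecoxib",
                                             profile = "hypertension",
                                             structure = "exactly_additive")),
                    seed = 4)
  pop <- simulate_outcomes(generate_population(cfg))
  dir <- tempfile("claims")
  write_claims(pop, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "persons.csv", "dispensings.csv", "hospitalizations.csv",
    "ground_truth.json")))))
  back <- read_claims(dir)
  expect_equal(back$persons$person_id, pop$persons$person_id)
  expect_equal(back$dispensings$dispense_date,
               pop$dispensings$dispense_date)
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
  expect_equal(gt$interactions[[1]]$implied_or11,
               1.2 + 1.4 - 1)  # celecoxib OR + hypertension OR - 1
  expect_equal(gt$interactions[[1]]$true_reri, 0)
  unlink(dir, recursive = TRUE)
})

test_that("null model: MI incidence matches the baseline odds", {
  cfg <- sim_config(n_persons = 600, study_start = as.Date("1993-01-01"),
                    study_end = as.Date("1993-12-31"),
                    coverage_start_range = c(-730L, -400L),
                    baseline_daily_odds = 1e-3, annual_death_prob = 0,
                    or_nsaid = c(celecoxib = 1, diclofenac = 1,
                                 ibuprofen = 1, naproxen = 1,
                                 rofecoxib = 1, other_nsaid = 1),
                    or_comorbidity = c(
                      diabetes = 1, hyperlipidemia = 1, hypertension = 1,
                      previous_mi = 1, chd = 1, cerebrovascular = 1,
                      chf = 1, pvd = 1, copd = 1, gi_ulcer = 1,
                      gi_bleed = 1, renal_failure = 1,
                      rheumatoid_arthritis = 1),
                    seed = 77)
  pop <- simulate_outcomes(generate_population(cfg))
  mi <- attr(pop$hospitalizations, "mi_truth")
  # person-days at risk: coverage within study, censored at first event
  s0 <- as.Date("1993-01-01"); s1 <- as.Date("1993-12-31")
  lo <- pmax(pop$persons$coverage_start, s0)
  hi <- pmin(pop$persons$coverage_end, s1)
  ev <- mi$admission_date[match(pop$persons$person_id, mi$person_id)]
  hi2 <- pmin(hi, ev, na.rm = TRUE)
  days <- sum(pmax(as.numeric(hi2 - lo) + 1, 0))
  rate <- nrow(mi) / days
  p_true <- 1e-3 / (1 + 1e-3)
  band <- 2.58 * sqrt(p_true * (1 - p_true) / days)
  expect_lt(abs(rate - p_true), band)
})

test_that("per-day event odds match configured ORs across strata", {
  # one drug, one comorbidity, elevated baseline; >= 1e5 person-days
  cfg <- sim_config(n_persons = 700, study_start = as.Date("1993-01-01"),
                    study_end = as.Date("1993-12-31"),
                    coverage_start_range = c(-730L, -400L),
                    baseline_daily_odds = 2e-3, annual_death_prob = 0,
                    nsaid_spell_rate = 3, refills_mean = 6,
                    market_shares = c(celecoxib = 1, diclofenac = 0,
                                      ibuprofen = 0, naproxen = 0,
                                      rofecoxib = 0, other_nsaid = 0),
                    switch_prob = 0,
                    comorbidity_prevalence = c(hypertension = 0.5),
                    or_comorbidity = c(hypertension = 3),
                    or_nsaid = c(celecoxib = 2, diclofenac = 1,
                                 ibuprofen = 1, naproxen = 1,
                                 rofecoxib = 1, other_nsaid = 1),
                    aspirin_user_prob = 0, aspirin_cv_extra = 0,
                    seed = 31)
  pop <- simulate_outcomes(generate_population(cfg))
  mi <- attr(pop$hospitalizations, "mi_truth")
  s0 <- as.Date("1993-01-01"); s1 <- as.Date("1993-12-31")
  onset <- attr(pop$comorbidities, "onset")
  disp <- pop$dispensings
  events <- integer(4); days <- numeric(4)   # strata: E x C
  for (i in seq_len(nrow(pop$persons))) {
    pid <- pop$persons$person_id[i]
    lo <- max(pop$persons$coverage_start[i], s0)
    hi <- min(pop$persons$coverage_end[i], s1)
    if (hi < lo) next
    ev <- mi$admission_date[match(pid, mi$person_id)]
    hi2 <- min(hi, ev, na.rm = TRUE)
    dd <- seq(lo, hi2, by = 1)
    pd <- disp[disp$person_id == pid & disp$drug == "celecoxib", ]
    expos <- rep(FALSE, length(dd))
    if (nrow(pd)) {
      e <- build_episodes(pd)
      for (k in seq_len(nrow(e)))
        expos[dd >= e$start[k] & dd <= e$end[k]] <- TRUE
    }
    com <- isTRUE(pop$comorbidities$hypertension[i]) &
      dd >= onset$hypertension[i]
    com[is.na(com)] <- FALSE
    stratum <- 1 + expos + 2 * com
    for (s in 1:4) days[s] <- days[s] + sum(stratum == s)
    if (!is.na(ev) && ev >= lo && ev <= hi2) {
      s_ev <- stratum[match(ev, dd)]
      events[s_ev] <- events[s_ev] + 1
    }
  }
  expect_gt(sum(days), 1e5)
  odds_cfg <- 2e-3 * c(1, 2, 3, 6)
  p_cfg <- odds_cfg / (1 + odds_cfg)
  for (s in 1:4) {
    band <- 2.58 * sqrt(p_cfg[s] * (1 - p_cfg[s]) / days[s])
    expect_lt(abs(events[s] / days[s] - p_cfg[s]), band + 1e-12)
  }
})

test_that("condensed NCC generator has exact risk-set structure", {
  d <- simulate_ncc_study(n_persons = 3000, n_days = 60,
                          baseline_odds = 0.003, seed = 12)
  expect_true(all(tapply(d$case, d$set_id, sum) == 1))
  expect_true(all(tapply(d$case, d$set_id, length) <= 11))
  expect_equal(d$product, d$exposed * d$profile)
  tr <- attr(d, "truth")
  expect_equal(tr$or11, tr$or_exposure * tr$or_profile)
})
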