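entry <- as.Date("1993-06-01")
index <- as.Date("1994-06-01")
p1 <- fx_person("A", birth = "1920-06-15")

test_that("mediating comorbidities are assessed only before cohort entry", {
  h_after <- fx_hosp("A", "1993-09-01", "1993-09-05", "401.9")
  h_before <- fx_hosp("A", "1993-01-10", "1993-01-14", "401.9")
  cv_after <- ascertain_covariates(p1, empty_disp(), h_after,
                                   index, entry)
  cv_before <- ascertain_covariates(p1, empty_disp(), h_before,
                                    index, entry)
  expect_false(cv_after$hypertension)
  expect_true(cv_before$hypertension)
  # mediator status never depends on data dated in (entry, index]
  h_both <- rbind(h_before, fx_hosp("A", "1994-01-01", "1994-01-05",
                                    "428.0"))
  cv_both <- ascertain_covariates(p1, empty_disp(), h_both, index,
                                  entry)
  expect_false(cv_both$chf)
  expect_true(cv_both$hypertension)
})

test_that("30-day drug windows behave as specified", {
  mk <- function(days_before)
    fx_disp("A", "marker_clopidogrel", index - days_before)
  cv10 <- ascertain_covariates(p1, mk(10), empty_hosp(), index, entry)
  cv45 <- ascertain_covariates(p1, mk(45), empty_hosp(), index, entry)
  expect_true(cv10$clopidogrel_30d)
  expect_false(cv45$clopidogrel_30d)
  co <- fx_disp("A", "marker_corticosteroid", index - 20)
  expect_true(ascertain_covariates(p1, co, empty_hosp(), index,
                                    entry)$corticosteroids_30d)
})

test_that("COPD drugs count only in the year before index, diagnoses always", {
  d_old <- fx_disp("A", "marker_respiratory_drug", index - 500)
  d_new <- fx_disp("A", "marker_respiratory_drug", index - 100)
  expect_false(ascertain_covariates(p1, d_old, empty_hosp(), index,
                                     entry)$copd)
  expect_true(ascertain_covariates(p1, d_new, empty_hosp(), index,
                                   entry)$copd)
  h_old <- fx_hosp("A", "1991-05-01", "1991-05-06", "496")
  expect_true(ascertain_covariates(p1, d_old[0, ], h_old, index,
                                    entry)$copd)
})

test_that("strict CHD needs leading position, procedure, or 30-day drugs", {
  h2 <- fx_hosp("A", "1993-02-01", "1993-02-10", "780.9;414.0")  # pos 2
  broad <- ascertain_covariates(p1, empty_disp(), h2, index, entry,
                                chd_definition = "broad")
  strict <- ascertain_covariates(p1, empty_disp(), h2, index,
                                 entry, chd_definition = "strict")
  expect_true(broad$chd)
  expect_false(strict$chd)
  h1 <- fx_hosp("A", "1993-02-01", "1993-02-10", "411.1;780.9")  # leading
  expect_true(ascertain_covariates(p1, empty_disp(), h1, index,
                                    entry, "strict")$chd)
  hp <- fx_hosp("A", "1993-02-01", "1993-02-10", "786.5", proc = "480.2")
  expect_true(ascertain_covariates(p1, empty_disp(), hp, index,
                                    entry, "strict")$chd)
  d30 <- fx_disp("A", "marker_antianginal", index - 15)
  expect_true(ascertain_covariates(p1, d30, empty_hosp(), index, entry,
                                    "strict")$chd)
  d45 <- fx_disp("A", "marker_antianginal", index - 45)
  expect_false(ascertain_covariates(p1, d45, empty_hosp(), index, entry,
                                    "strict")$chd)
})

test_that("previous MI comes from admissions strictly before the index one", {
  h <- rbind(fx_hosp("A", "1992-03-01", "1992-03-08", "410.1"),
             fx_hosp("A", index, index + 6, "410.9"))
  cv <- ascertain_covariates(p1, empty_disp(), h, index, entry)
  expect_true(cv$previous_mi)
  cv2 <- ascertain_covariates(p1, empty_disp(), h[2, ], index,
                              entry)
  expect_false(cv2$previous_mi)
})

test_that("age at index is in completed years", {
  cv <- ascertain_covariates(fx_person("A", birth = "1920-06-15"),
                             empty_disp(), empty_hosp(),
                             as.Date("1994-06-14"), entry)
  expect_equal(cv$age_at_index, 73)
  cv2 <- ascertain_covariates(fx_person("A", birth = "1920-06-15"),
                              empty_disp(), empty_hosp(),
                              as.Date("1994-06-15"), entry)
  expect_equal(cv2$age_at_index, 74)
})

test_that("strict CHD implies broad CHD on synthetic data", {
  cfg <- sim_config(n_persons = 150, study_end = as.Date("1995-12-31"),
                    baseline_daily_odds = 5e-4, nsaid_spell_rate = 1.5,
                    seed = 3)
  pop <- simulate_outcomes(generate_population(cfg))
  coh <- assemble_cohort(pop$persons, pop$dispensings,
                         pop$hospitalizations, cfg$study_start,
                         cfg$study_end)
  expect_gt(nrow(coh$cohort), 5)
  idx <- coh$cohort$exit_date
  for (i in seq_len(min(30, nrow(coh$cohort)))) {
    pid <- coh$cohort$person_id[i]
    pd <- pop$dispensings[pop$dispensings$person_id == pid, ]
    ph <- pop$hospitalizations[pop$hospitalizations$person_id == pid, ]
    pr <- pop$persons[pop$persons$person_id == pid, ]
    b <- ascertain_covariates(pr, pd, ph, idx[i],
                              coh$cohort$entry_date[i], "broad")
    s <- ascertain_covariates(pr, pd, ph, idx[i],
                              coh$cohort$entry_date[i], "strict")
    expect_true(b$chd >= s$chd)
  }
})
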