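test_that("daily dose is strength x quantity / days supplied", {
  expect_equal(daily_dose(200, 30, 30), 200)
  expect_equal(daily_dose(25, 60, 30), 50)
  expect_equal(daily_dose(500, 45, 30), 750)
  expect_error(daily_dose(200, 30, 0), "days_supplied")
})

test_that("abutting refills merge into one episode", {
  d <- fx_disp("P1", "naproxen", c("1993-01-01", "1993-01-31"))
  e <- build_episodes(d)
  expect_equal(length(unique(e$episode)), 1L)
  expect_equal(min(e$start), as.Date("1993-01-01"))
  expect_equal(max(e$end), as.Date("1993-03-01"))  # days 0-59
})

test_that("overlapping same-drug refill is shifted forward (stockpiling)", {
  d <- fx_disp("P1", "naproxen", c("1993-01-01", "1993-01-21"))
  e <- build_episodes(d)
  expect_equal(length(unique(e$episode)), 1L)
  # second 30-day supply starts the day after the first ends
  expect_equal(as.numeric(max(e$end) - min(e$start)) + 1, 60)
})

test_that("a different NSAID terminates the active episode the day before", {
  d <- rbind(fx_disp("P1", "naproxen", "1993-01-01"),
             fx_disp("P1", "celecoxib", "1993-01-11"))
  e <- build_episodes(d)
  nap <- e[e$drug == "naproxen", ]
  cel <- e[e$drug == "celecoxib", ]
  expect_equal(max(nap$end), as.Date("1993-01-10"))
  expect_equal(min(cel$start), as.Date("1993-01-11"))
})

test_that("same-day fills of two NSAIDs leave exactly one exposed drug", {
  d <- rbind(fx_disp("P1", "naproxen", "1993-01-01"),
             fx_disp("P1", "celecoxib", "1993-01-01"))
  e <- build_episodes(d)
  expect_equal(length(unique(e$drug)), 1L)
})

test_that("NSAID refill gaps end episodes; aspirin has a 7-day grace", {
  # any positive gap splits NSAID episodes
  d <- fx_disp("P1", "ibuprofen", c("1993-01-01", "1993-02-01"))
  expect_equal(length(unique(build_episodes(d)$episode)), 2L)
  # aspirin: 7-day gap bridges, 8-day gap splits
  a7 <- fx_disp("P1", "aspirin", c("1993-01-01", "1993-02-07"),
                strength = 80)
  a8 <- fx_disp("P1", "aspirin", c("1993-01-01", "1993-02-08"),
                strength = 80)
  e7 <- build_episodes(a7)
  e8 <- build_episodes(a8)
  expect_equal(length(unique(e7$episode)), 1L)
  expect_equal(length(unique(e8$episode)), 2L)
  # bridged gap days remain exposed
  expect_true(any(e7$start <= as.Date("1993-02-03") &
                    e7$end >= as.Date("1993-02-03")))
})

test_that("dose changes create segments carrying the latest dose", {
  d <- rbind(fx_disp("P1", "celecoxib", "1993-01-01", strength = 200),
             fx_disp("P1", "celecoxib", "1993-01-31", strength = 400))
  e <- build_episodes(d)
  expect_equal(length(unique(e$episode)), 1L)
  expect_equal(e$daily_dose, c(200, 400))
})

test_that("episode construction is invariant to dispensing input order", {
  set.seed(42)
  for (i in 1:50) {
    d <- fuzz_stream()
    e1 <- build_episodes(d)
    e2 <- build_episodes(d[sample(nrow(d)), ])
    rownames(e1) <- rownames(e2) <- NULL
    expect_equal(e1, e2)
  }
})

test_that("episodes of distinct study NSAIDs never overlap", {
  set.seed(7)
  for (i in 1:200) {
    e <- build_episodes(fuzz_stream())
    e <- e[e$drug != "aspirin", ]
    if (nrow(e) < 2) next
    days <- unlist(lapply(seq_len(nrow(e)), function(k)
      seq(as.integer(e$start[k]), as.integer(e$end[k]))))
    expect_false(anyDuplicated(days) > 0)
  }
})

test_that("exposure classification windows follow the two variants", {
  # supply covers days 0-29; classify relative to its end (day 29)
  d <- fx_disp("P1", "celecoxib", "1993-01-01")
  e <- build_episodes(d)
  pA <- parametrization("index_day_only")
  pB <- parametrization("index_or_7_prior")
  cls <- function(p, idx) {
    v <- classify_exposure(e, as.Date("1993-01-30") + idx, p)
    v$category[v$drug == "celecoxib"]
  }
  expect_equal(cls(pA, -1), "current")          # on supply
  expect_equal(cls(pA, 4), "recent")            # ends 5 days before index
  expect_equal(cls(pB, 4), "current")
  expect_equal(cls(pA, 99), "past")             # 100 days before index
  expect_equal(cls(pB, 99), "past")
  expect_equal(cls(pA, 199), "none")            # 200 days before index
  expect_equal(cls(pB, 199), "none")
})

test_that("current dose is the dose of the most recent segment", {
  d <- rbind(fx_disp("P1", "celecoxib", "1993-01-01", strength = 200),
             fx_disp("P1", "celecoxib", "1993-01-31", strength = 400))
  e <- build_episodes(d)
  v <- classify_exposure(e, as.Date("1993-02-15"),
                         parametrization("index_day_only", "daily_dose"))
  expect_equal(v$current_dose[v$drug == "celecoxib"], 400)
  # binary parametrization reports no dose
  vb <- classify_exposure(e, as.Date("1993-02-15"),
                          parametrization("index_day_only", "binary_use"))
  expect_equal(vb$current_dose[vb$drug == "celecoxib"], 0)
})

test_that("at most one NSAID is current under the 7-day window", {
  d <- rbind(fx_disp("P1", "naproxen", "1993-01-01"),
             fx_disp("P1", "celecoxib", "1993-01-15"))
  e <- build_episodes(d)
  # index 3 days after the switch: naproxen ended 4 days ago, celecoxib on
  v <- classify_exposure(e, as.Date("1993-01-18"),
                         parametrization("index_or_7_prior"))
  expect_equal(sum(v$category == "current"), 1L)
  expect_equal(v$category[v$drug == "celecoxib"], "current")
  expect_equal(v$category[v$drug == "naproxen"], "recent")
})

test_that("cardioprotective aspirin status follows dose bounds and window", {
  mk <- function(strength, quantity = 30, ds = 30)
    fx_disp("P1", "aspirin", "1993-01-01", strength = strength,
            quantity = quantity, days_supplied = ds)
  idx <- as.Date("1993-01-15")
  expect_true(classify_aspirin(mk(80), idx))
  expect_true(classify_aspirin(mk(650), idx))
  expect_false(classify_aspirin(mk(975), idx))
  # 80 mg every other day averages 40 mg/day: still cardioprotective
  expect_true(classify_aspirin(mk(80, quantity = 15), idx))
  expect_false(classify_aspirin(fx_disp("P1", "naproxen", "1993-01-01"),
                                idx))
  expect_false(classify_aspirin(mk(80)[0, ], idx))
  # episode ending within the 30-day pre-index window still counts
  expect_true(classify_aspirin(mk(80), as.Date("1993-02-20")))
  expect_false(classify_aspirin(mk(80), as.Date("1993-04-01")))
})
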