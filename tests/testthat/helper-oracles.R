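# Independent oracles and small fixture builders used across tests.

# brute-force conditional log-likelihood: direct enumeration over each set
oracle_cond_loglik <- function(beta, x, case, set) {
  ll <- 0
  for (g in unique(set)) {
    rows <- which(set == g)
    eta <- as.numeric(x[rows, , drop = FALSE] %*% beta)
    ll <- ll + eta[case[rows] == 1] - log(sum(exp(eta)))
  }
  ll
}

# generic-optimizer maximization of the same likelihood (independent of the
# package's Newton-Raphson path); central-difference gradient of the
# enumerated likelihood gives the optimizer enough precision
oracle_cond_fit <- function(x, case, set) {
  fn <- function(b) -oracle_cond_loglik(b, x, case, set)
  gr <- function(b) {
    h <- 1e-5
    vapply(seq_along(b), function(j) {
      e <- replace(numeric(length(b)), j, h)
      (fn(b + e) - fn(b - e)) / (2 * h)
    }, numeric(1))
  }
  par <- stats::optim(rep(0, ncol(x)), fn = fn, gr = gr, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-15))$par
  # polish: BFGS stops on function-value change, which localises a flat
  # optimum only to ~1e-6; a few Newton steps on finite-difference
  # derivatives of the enumerated likelihood pin it down further
  for (it in 1:8) {
    g <- gr(par)
    if (max(abs(g)) < 1e-9) break
    H <- vapply(seq_along(par), function(j) {
      e <- replace(numeric(length(par)), j, 1e-4)
      (gr(par + e) - gr(par - e)) / (2e-4)
    }, numeric(length(par)))
    step <- tryCatch(solve((H + t(H)) / 2, g), error = function(e) NULL)
    if (is.null(step)) break
    cand <- par - step
    if (fn(cand) <= fn(par) + 1e-12) par <- cand else break
  }
  par
}

# random small matched-set dataset (sets of size <= 11, <= 3 covariates)
random_cc_dataset <- function(n_sets = 8, max_m = 10, k = 3) {
  rows <- list()
  for (s in seq_len(n_sets)) {
    m <- sample(1:max_m, 1)
    x <- matrix(rnorm(k * (m + 1)), m + 1, k)
    x[, 1] <- rbinom(m + 1, 1, 0.4)     # keep one binary column
    rows[[s]] <- data.frame(set_id = s, case = c(1L, rep(0L, m)), x)
  }
  d <- do.call(rbind, rows)
  names(d)[3:(2 + k)] <- paste0("x", seq_len(k))
  d
}

# minimal persons/dispensings/hospitalizations fixtures -----------------------

fx_person <- function(id = "P1", birth = "1920-06-15",
                      cov_start = "1991-01-01", cov_end = "1997-06-30",
                      sex = "M", death = NA) {
  data.frame(person_id = id, birth_date = as.Date(birth), sex = sex,
             coverage_start = as.Date(cov_start),
             coverage_end = as.Date(cov_end),
             death_date = as.Date(death))
}

fx_disp <- function(id, drug, date, strength = 200, quantity = 30,
                    days_supplied = 30) {
  data.frame(person_id = id, drug = drug, dispense_date = as.Date(date),
             strength = strength, quantity = quantity,
             days_supplied = days_supplied)
}

fx_hosp <- function(id, adm, dis, dx, proc = "", transfer = FALSE) {
  data.frame(person_id = id, admission_date = as.Date(adm),
             discharge_date = as.Date(dis), diagnoses = dx,
             procedures = proc, transfer_flag = transfer)
}

empty_hosp <- function() {
  data.frame(person_id = character(),
             admission_date = as.Date(integer(), origin = "1970-01-01"),
             discharge_date = as.Date(integer(), origin = "1970-01-01"),
             diagnoses = character(), procedures = character(),
             transfer_flag = logical())
}

# fuzzed dispensing stream over integer days
fuzz_stream <- function() {
  m <- sample(1:8, 1)
  data.frame(drug = sample(c(nsaid_groups(), "aspirin"), m, TRUE),
             dispense_date = sample(0:400, m, TRUE),
             strength = sample(c(25, 100, 200, 500), m, TRUE),
             quantity = sample(c(10, 30, 60), m, TRUE),
             days_supplied = sample(c(5L, 10L, 30L, 60L), m, TRUE))
}

# last NSAID-supplied day per drug group, derived directly from episodes
last_supply_delta <- function(episodes, idx) {
  out <- rep(NA_integer_, 6)
  names(out) <- nsaid_groups()
  for (g in nsaid_groups()) {
    sel <- episodes$drug == g & as.integer(episodes$start) <= idx
    if (!any(sel)) next
    out[g] <- idx - max(pmin(as.integer(episodes$end[sel]), idx))
  }
  out
}

empty_disp <- function() {
  data.frame(person_id = character(), drug = character(),
             dispense_date = as.Date(integer(), origin = "1970-01-01"),
             strength = numeric(), quantity = numeric(),
             days_supplied = integer())
}
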