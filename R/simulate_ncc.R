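#' Simulate a nested case-control study with known interaction structure
#'
#' A condensed generator for estimator calibration: a closed cohort of
#' persons with a time-fixed binary drug exposure and comorbidity profile
#' is followed for \code{n_days} days under the per-day Bernoulli event
#' model (odds = baseline odds x OR(exposure, profile), with the joint-cell
#' multiplier set by the interaction structure). Each event day defines a
#' risk set from which matched controls are drawn without replacement among
#' persons still event-free at that follow-up time, yielding genuine
#' incidence-density sampling: later cases serve as earlier controls and a
#' person may appear in several sets.
#'
#' @param n_persons Cohort size.
#' @param n_days Follow-up length in days.
#' @param baseline_odds Baseline per-day odds of the event.
#' @param p_exposed,p_profile Prevalence of exposure and profile
#'   (independent).
#' @param or_exposure,or_profile Marginal odds ratios.
#' @param structure Interaction structure for the joint cell, see
#'   [implied_or11()].
#' @param or11 Joint OR when \code{structure = "custom"}.
#' @param ratio Controls per case.
#' @param max_sets Optional cap on the number of sets returned.
#' @param seed Optional seed.
#' @return Data frame \code{set_id}, \code{case}, \code{exposed},
#'   \code{profile}, \code{product}; attribute \code{"truth"} carries the
#'   generating odds ratios, implied OR11 and true RERI.
#' @export
simulate_ncc_study <- function(n_persons = 8000, n_days = 80,
                               baseline_odds = 0.002, p_exposed = 0.25,
                               p_profile = 0.30, or_exposure = 2,
                               or_profile = 3,
                               structure = c("exactly_multiplicative",
                                             "exactly_additive", "custom"),
                               or11 = NULL, ratio = 10, max_sets = Inf,
                               seed = NULL) {
  structure <- match.arg(structure)
  if (!is.null(seed)) set.seed(as.integer(seed))
  or11 <- implied_or11(or_exposure, or_profile, structure, or11)
  E <- stats::runif(n_persons) < p_exposed
  C <- stats::runif(n_persons) < p_profile
  mult <- rep(1, n_persons)
  mult[E & !C] <- or_exposure
  mult[!E & C] <- or_profile
  mult[E & C] <- or11
  p <- baseline_odds * mult / (1 + baseline_odds * mult)
  event_day <- stats::rgeom(n_persons, p) + 1L   # day of event, maybe > n_days
  is_case <- event_day <= n_days
  case_idx <- which(is_case)
  case_idx <- case_idx[order(event_day[case_idx], case_idx)]
  if (length(case_idx) > max_sets) case_idx <- case_idx[seq_len(max_sets)]
  ids <- vector("list", length(case_idx))
  sid <- vector("list", length(case_idx))
  for (s in seq_along(case_idx)) {
    i <- case_idx[s]
    t <- event_day[i]
    at_risk <- which(event_day > t)
    if (!length(at_risk)) next
    ctl <- if (length(at_risk) > ratio) sample(at_risk, ratio) else at_risk
    ids[[s]] <- c(i, ctl)
    sid[[s]] <- rep(s, 1L + length(ctl))
  }
  ids_v <- unlist(ids); sid_v <- unlist(sid)
  res <- data.frame(set_id = sid_v,
                    case = as.integer(!duplicated(sid_v)),
                    exposed = as.numeric(E[ids_v]),
                    profile = as.numeric(C[ids_v]))
  res$product <- res$exposed * res$profile
  attr(res, "truth") <- list(or_exposure = or_exposure,
                             or_profile = or_profile, or11 = or11,
                             reri = or11 - or_exposure - or_profile + 1,
                             structure = structure)
  res
}
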