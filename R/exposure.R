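#' Estimated daily dose of a dispensing
#'
#' Computes the estimated daily dose of a prescription fill as pill strength
#' times number of pills divided by number of days supplied.
#'
#' @param strength Pill strength in mg (positive).
#' @param quantity Number of pills dispensed (>= 1).
#' @param days_supplied Intended coverage of the fill in days (>= 1).
#' @return Daily dose in mg/day; vectorised over its arguments.
#' @examples
#' daily_dose(200, 30, 30)  # 200 mg/day
#' daily_dose(25, 60, 30)   # 50 mg/day
#' @export
daily_dose <- function(strength, quantity, days_supplied) {
  if (any(days_supplied <= 0))
    .stopf("`days_supplied` must be positive (got %s)",
           paste(utils::head(days_supplied[days_supplied <= 0], 3),
                 collapse = ", "))
  if (any(strength <= 0) || any(quantity < 1))
    .stopf("`strength` must be positive and `quantity` >= 1")
  strength * quantity / days_supplied
}

#' Build continuous exposure episodes from one person's dispensings
#'
#' Collapses a dispensing stream into episodes of continuous use, honouring
#' refill gaps, stockpiling, dose changes, and switches. Same-drug refills
#' whose supply periods abut or overlap merge into one episode; an overlapping
#' refill is shifted forward to start the day after the previous supply ends.
#' A refill gap larger than the grace period (0 days for study NSAIDs, 7 days
#' for aspirin) ends the episode; gap days bridged by the grace period remain
#' exposed at the previous dose. Dispensing a different study NSAID terminates
#' any active NSAID episode on the day before its dispense date, so episodes
#' of distinct study NSAIDs never overlap. Aspirin is processed as a separate
#' stream and neither terminates nor is terminated by NSAID dispensings.
#'
#' @param dispensings Data frame with columns \code{drug},
#'   \code{dispense_date} (Date or integer day), \code{strength},
#'   \code{quantity}, \code{days_supplied} for a single person.
#' @param nsaid_grace Maximum refill gap (days) preserving an NSAID episode.
#' @param aspirin_grace Maximum refill gap (days) preserving an aspirin
#'   episode.
#' @return Data frame of episode segments: \code{drug}, \code{episode}
#'   (id, unique within the stream), \code{start}, \code{end},
#'   \code{daily_dose}. A segment is a maximal run of days within an episode
#'   at one daily dose (the dose of the most recent contributing dispensing).
#' @export
build_episodes <- function(dispensings, nsaid_grace = 0, aspirin_grace = 7) {
  .assert_columns(dispensings,
                  c("drug", "dispense_date", "strength", "quantity",
                    "days_supplied"), "dispensings")
  date0 <- dispensings$dispense_date
  out <- .episodes_core(as.character(dispensings$drug), .as_day(date0),
                        daily_dose(dispensings$strength,
                                   dispensings$quantity,
                                   dispensings$days_supplied),
                        as.integer(dispensings$days_supplied),
                        nsaid_grace, aspirin_grace)
  data.frame(drug = out$drug, episode = out$episode,
             start = .restore_day(out$start, date0),
             end = .restore_day(out$end, date0),
             daily_dose = out$dose)
}

# vector core of the episode construction (integer days in, integer days out)
.episodes_core <- function(drug, d_all, dose_all, ds_all, nsaid_grace = 0,
                           aspirin_grace = 7) {
  keep <- .is_nsaid(drug) | drug == "aspirin"
  if (!any(keep)) {
    return(list(drug = character(), episode = integer(), start = integer(),
                end = integer(), dose = numeric()))
  }
  d_all <- d_all[keep]
  drug <- drug[keep]
  dose_all <- dose_all[keep]
  ds_all <- ds_all[keep]

  run <- function(idx, grace, cross_terminate) {
    o <- order(d_all[idx], drug[idx], dose_all[idx], ds_all[idx])
    idx <- idx[o]
    n <- length(idx)
    # grown output vectors; streams are short so simple appends are fine
    s_drug <- character(0); s_ep <- integer(0)
    s_start <- integer(0); s_end <- integer(0); s_dose <- numeric(0)
    act_drug <- NA_character_; act_end <- -Inf; ep <- 0L
    for (i in idx) {
      d <- d_all[i]; ds <- ds_all[i]; dg <- drug[i]; dose <- dose_all[i]
      if (!is.na(act_drug) && cross_terminate && dg != act_drug &&
          act_end >= d) {
        # switch: truncate active drug to the day before the new dispensing
        j <- length(s_end)
        while (j >= 1L && s_drug[j] == act_drug && s_start[j] > d - 1L) {
          s_start <- s_start[-j]; s_end <- s_end[-j]
          s_drug <- s_drug[-j]; s_ep <- s_ep[-j]; s_dose <- s_dose[-j]
          j <- j - 1L
        }
        if (j >= 1L && s_drug[j] == act_drug && s_end[j] > d - 1L)
          s_end[j] <- d - 1L
      }
      same <- !is.na(act_drug) && dg == act_drug &&
        d <= act_end + 1L + grace
      if (same) {
        new_start <- max(d, act_end + 1L)
        j <- length(s_end)
        if (new_start - 1L > s_end[j]) s_end[j] <- new_start - 1L # bridge gap
      } else {
        ep <- ep + 1L
        new_start <- d
      }
      s_drug <- c(s_drug, dg); s_ep <- c(s_ep, ep)
      s_start <- c(s_start, new_start)
      s_end <- c(s_end, new_start + ds - 1L)
      s_dose <- c(s_dose, dose)
      act_drug <- dg; act_end <- new_start + ds - 1L
    }
    list(drug = s_drug, episode = s_ep, start = s_start, end = s_end,
         dose = s_dose)
  }

  nsaid_idx <- which(.is_nsaid(drug))
  asp_idx <- which(drug == "aspirin")
  segs <- list()
  if (length(nsaid_idx))
    segs[[1L]] <- run(nsaid_idx, as.integer(nsaid_grace), TRUE)
  if (length(asp_idx)) {
    a <- run(asp_idx, as.integer(aspirin_grace), FALSE)
    a$episode <- a$episode + if (length(segs)) max(segs[[1L]]$episode) else 0L
    segs[[length(segs) + 1L]] <- a
  }
  out <- list(drug = unlist(lapply(segs, `[[`, "drug")),
              episode = unlist(lapply(segs, `[[`, "episode")),
              start = unlist(lapply(segs, `[[`, "start")),
              end = unlist(lapply(segs, `[[`, "end")),
              dose = unlist(lapply(segs, `[[`, "dose")))
  ok <- out$end >= out$start
  lapply(out, `[`, ok)
}

#' Exposure parametrization
#'
#' One of the four candidate definitions of "current" NSAID exposure: the
#' current window is either the index date alone or the index date or any of
#' the 7 prior days, and current exposure enters the model either as a binary
#' use indicator or as the current daily dose.
#'
#' @param current_window \code{"index_day_only"} or \code{"index_or_7_prior"}.
#' @param current_as \code{"binary_use"} or \code{"daily_dose"}.
#' @return An object of class \code{"parametrization"}.
#' @seealso [parametrizations()] for all four candidates.
#' @export
parametrization <- function(current_window = c("index_day_only",
                                               "index_or_7_prior"),
                            current_as = c("binary_use", "daily_dose")) {
  structure(list(current_window = match.arg(current_window),
                 current_as = match.arg(current_as)),
            class = "parametrization")
}

#' @rdname parametrization
#' @export
parametrizations <- function() {
  out <- list()
  for (w in c("index_day_only", "index_or_7_prior"))
    for (a in c("binary_use", "daily_dose"))
      out[[paste(a, w, sep = ".")]] <- parametrization(w, a)
  out
}

#' @export
print.parametrization <- function(x, ...) {
  cat("Exposure parametrization: current =", x$current_as,
      "in window", x$current_window, "\n")
  invisible(x)
}

#' Classify NSAID exposure at an index date
#'
#' Assigns each of the six NSAID groups one of the mutually exclusive
#' categories current / recent (1-30 days ago, or 8-30 under the 7-day
#' current window) / past (31-180 days ago) / none (no use in the last 180
#' days), based on the last exposed day at or before the index date.
#' Categories are assessed in that order so exactly one holds per group. At
#' most one NSAID group is current on any day: when the widened current
#' window catches two drugs around a switch, the most recently used drug is
#' current and the other falls through to recent.
#'
#' @param episodes Episode segments from [build_episodes()] (aspirin rows are
#'   ignored).
#' @param index_date Index date (Date or integer day).
#' @param p A [parametrization()].
#' @return Data frame with one row per NSAID group: \code{drug},
#'   \code{category}, and \code{current_dose} (mg/day; non-zero only when
#'   category is current and doses are modelled; always 0 for
#'   \code{other_nsaid}, whose exposure is binary).
#' @export
classify_exposure <- function(episodes, index_date, p = parametrization()) {
  stopifnot(inherits(p, "parametrization"))
  e_dose <- if (is.data.frame(episodes)) episodes$daily_dose else
    episodes$dose
  out <- .classify_core(as.character(episodes$drug),
                        .as_day(episodes$start), .as_day(episodes$end),
                        e_dose, .as_day(index_date),
                        cur_lim = if (p$current_window ==
                                      "index_or_7_prior") 7L else 0L,
                        dose_mode = p$current_as == "daily_dose")
  data.frame(drug = nsaid_groups(), category = out$category,
             current_dose = out$current_dose)
}

.classify_core <- function(e_drug, e_start, e_end, e_dose, idx, cur_lim,
                           dose_mode) {
  groups <- nsaid_groups()
  cat_out <- rep("none", length(groups))
  dose_out <- numeric(length(groups))
  delta_out <- rep(NA_integer_, length(groups))
  if (length(e_drug)) {
    in_past <- e_start <= idx
    for (k in seq_along(groups)) {
      g <- groups[k]
      sel <- which(e_drug == g & in_past)
      if (!length(sel)) next
      last_day <- pmin(e_end[sel], idx)
      L <- max(last_day)
      delta <- idx - L
      delta_out[k] <- delta
      if (delta <= cur_lim) {
        cat_out[k] <- "current"
        if (dose_mode && g != "other_nsaid") {
          at <- sel[last_day == L]
          dose_out[k] <- e_dose[at[which.max(e_start[at])]]
        }
      } else if (delta <= 30L) {
        cat_out[k] <- "recent"
      } else if (delta <= 180L) {
        cat_out[k] <- "past"
      }
    }
    # at most one NSAID may be current on any day: with a widened current
    # window a recent switch can put two drugs in range; the most recently
    # used one wins and the other falls through to the next category
    cur <- which(cat_out == "current")
    if (length(cur) > 1L) {
      keep <- cur[order(delta_out[cur], cur)][1L]
      for (k in setdiff(cur, keep)) {
        cat_out[k] <- "recent"
        dose_out[k] <- 0
      }
    }
  }
  list(category = cat_out, current_dose = dose_out,
       days_since_last = delta_out)
}

#' Current cardioprotective aspirin status at an index date
#'
#' TRUE when an aspirin exposure episode at a cardioprotective daily dose
#' (40 to 650 mg/day; 80 mg every other day averages to 40 mg/day) overlaps
#' the 30-day window ending at the index date. Episodes are built with the
#' 7-day aspirin refill grace period.
#'
#' @param dispensings One person's dispensings (non-aspirin rows ignored), or
#'   \code{NULL} when \code{episodes} is supplied.
#' @param index_date Index date.
#' @param dose_range Inclusive cardioprotective daily-dose bounds (mg/day).
#' @param window_days Length of the pre-index ascertainment window.
#' @param episodes Optional precomputed segments from [build_episodes()].
#' @return Logical scalar.
#' @export
classify_aspirin <- function(dispensings, index_date,
                             dose_range = c(40, 650), window_days = 30,
                             episodes = NULL) {
  if (is.null(episodes)) {
    if (is.null(dispensings) || !nrow(dispensings)) return(FALSE)
    episodes <- build_episodes(dispensings[dispensings$drug == "aspirin", ,
                                           drop = FALSE])
  }
  e_dose <- if (is.data.frame(episodes)) episodes$daily_dose else
    episodes$dose
  if (!length(e_dose)) return(FALSE)
  idx <- .as_day(index_date)
  sel <- episodes$drug == "aspirin" &
    e_dose >= dose_range[1] &
    e_dose <= dose_range[2] &
    .as_day(episodes$start) <= idx &
    .as_day(episodes$end) >= idx - window_days
  any(sel)
}
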