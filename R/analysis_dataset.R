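#' Build the analysis dataset for matched sets under a parametrization
#'
#' Joins each set member's exposure vector at its index date (current /
#' recent / past indicators for the six NSAID groups, with current coded as
#' binary use or daily dose according to the parametrization) with the
#' confounder vector from [ascertain_covariates()]. Exposure episodes are
#' built once per person and reused across index dates.
#'
#' @param sets Matched sets from [sample_controls()].
#' @param cohort Cohort table (provides entry dates).
#' @param persons,dispensings,hospital_episodes Claims tables.
#' @param p A [parametrization()].
#' @param chd_definition \code{"broad"} or \code{"strict"}.
#' @return Data frame with \code{set_id}, \code{case}, \code{person_id},
#'   per-drug columns \code{<drug>_current}, \code{<drug>_current_bin},
#'   \code{<drug>_recent}, \code{<drug>_past}, and the confounders.
#'   \code{<drug>_current} carries the dose (mg/day) under dose
#'   parametrizations and the 0/1 use indicator otherwise;
#'   \code{<drug>_current_bin} is always the 0/1 indicator (used to form
#'   binary product terms).
#' @export
build_analysis_dataset <- function(sets, cohort, persons, dispensings,
                                   hospital_episodes, p = parametrization(),
                                   chd_definition = "broad") {
  ctx <- .member_context(sets, cohort, persons, dispensings,
                         hospital_episodes)
  out <- cbind(data.frame(set_id = sets$set_id, case = sets$case,
                          person_id = sets$person_id),
               .exposure_columns(sets, ctx, p),
               .covariate_columns(sets, ctx, chd_definition))
  rownames(out) <- NULL
  out
}

# per-member claims lookup shared by exposure and covariate construction
.member_context <- function(sets, cohort, persons, dispensings,
                            hospital_episodes) {
  if (!nrow(sets)) .stopf("`sets` is empty")
  d_by <- split(seq_len(nrow(dispensings)), dispensings$person_id)
  h_by <- split(seq_len(nrow(hospital_episodes)),
                hospital_episodes$person_id)
  eps_cache <- new.env(parent = emptyenv())
  d_empty <- dispensings[0, , drop = FALSE]
  h_empty <- hospital_episodes[0, , drop = FALSE]
  list(
    entry = cohort$entry_date[match(sets$person_id, cohort$person_id)],
    prow = match(sets$person_id, persons$person_id),
    persons = persons,
    disp = function(pid) {
      rows <- d_by[[pid]]
      if (is.null(rows)) d_empty else dispensings[rows, , drop = FALSE]
    },
    hosp = function(pid) {
      rows <- h_by[[pid]]
      if (is.null(rows)) h_empty else
        hospital_episodes[rows, , drop = FALSE]
    },
    episodes = function(pid, pd) {
      e <- eps_cache[[pid]]
      if (is.null(e)) {
        e <- build_episodes(pd)
        eps_cache[[pid]] <- e
      }
      e
    })
}

.exposure_columns <- function(sets, ctx, p) {
  stopifnot(inherits(p, "parametrization"))
  groups <- nsaid_groups()
  n <- nrow(sets)
  expo <- matrix(0, n, 3L * length(groups))
  colnames(expo) <- as.vector(t(outer(groups,
                                      c("_current", "_recent", "_past"),
                                      paste0)))
  cur_bin <- matrix(0, n, length(groups),
                    dimnames = list(NULL, paste0(groups, "_current_bin")))
  for (r in seq_len(n)) {
    pid <- as.character(sets$person_id[r])
    eps <- ctx$episodes(pid, ctx$disp(pid))
    ev <- classify_exposure(eps, sets$index_date[r], p)
    for (k in seq_along(groups)) {
      cat_k <- ev$category[k]
      if (cat_k == "current") {
        cur_bin[r, k] <- 1
        expo[r, 3L * k - 2L] <- if (p$current_as == "daily_dose" &&
                                    groups[k] != "other_nsaid")
          ev$current_dose[k] else 1
      } else if (cat_k == "recent") expo[r, 3L * k - 1L] <- 1
      else if (cat_k == "past") expo[r, 3L * k] <- 1
    }
  }
  cbind(as.data.frame(expo), as.data.frame(cur_bin))
}

.covariate_columns <- function(sets, ctx, chd_definition) {
  n <- nrow(sets)
  cov_rows <- vector("list", n)
  for (r in seq_len(n)) {
    pid <- as.character(sets$person_id[r])
    cov_rows[[r]] <- ascertain_covariates(
      ctx$persons[ctx$prow[r], , drop = FALSE], ctx$disp(pid),
      ctx$hosp(pid), sets$index_date[r], ctx$entry[r],
      chd_definition = chd_definition)
  }
  covs <- do.call(rbind, cov_rows)
  for (nm in names(covs)) covs[[nm]] <- as.numeric(covs[[nm]])
  covs
}

#' Base-model formula for an analysis dataset
#'
#' Builds \code{case ~ exposure terms + confounders}. Columns that vary
#' within fewer than \code{min_informative_sets} matched sets are dropped:
#' under the conditional likelihood such near-degenerate columns carry
#' almost no information and routinely produce quasi-separation in
#' desk-scale synthetic runs.
#'
#' @param data Output of [build_analysis_dataset()].
#' @param min_informative_sets Minimum number of sets in which a column
#'   must vary to enter the model.
#' @return A formula.
#' @export
base_model_formula <- function(data, min_informative_sets = 8) {
  groups <- nsaid_groups()
  expo <- as.vector(t(outer(groups, c("_current", "_recent", "_past"),
                            paste0)))
  confs <- c("age_at_index", names(comorbidity_definitions()),
             "corticosteroids_30d", "clopidogrel_30d", "aspirin_30d")
  keep <- intersect(c(expo, confs), names(data))
  sid <- data$set_id
  keep <- keep[vapply(keep, function(cl) {
    v <- data[[cl]]
    rng <- tapply(v, sid, function(z) max(z) - min(z))
    sum(rng > 0) >= min_informative_sets
  }, logical(1))]
  if (!length(keep)) .stopf("no informative model columns")
  stats::reformulate(keep, response = "case")
}
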