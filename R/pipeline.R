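#' Run the end-to-end nested case-control interaction analysis
#'
#' Orchestrates the full pipeline: (simulate or ingest claims tables) ->
#' outcome ascertainment -> new-user cohort -> risk-set matched sampling ->
#' analysis datasets under the four candidate NSAID exposure
#' parametrizations -> base-model fits ranked by AIC -> staged product-term
#' interaction analyses. The primary interaction analysis uses the
#' best-fitting base parametrization, the secondary uses the worst-fitting
#' one, and a sensitivity analysis reruns the primary with the strict
#' coronary-heart-disease definition. AIC ties are broken in favour of
#' fewer parameters.
#'
#' @param population A \code{claims_population} (from
#'   [generate_population()] + [simulate_outcomes()] or assembled from
#'   [read_claims()] tables); alternatively supply \code{config} to
#'   simulate one.
#' @param config A [sim_config()] used when \code{population} is NULL.
#' @param profiles Profile columns tested for interaction with each common
#'   NSAID (defaults to hypertension, CHD, previous MI, and current
#'   cardioprotective aspirin).
#' @param ratio Controls per case.
#' @param seed Seed for control sampling (defaults to the config seed + 4).
#' @param analyses Subset of \code{c("primary", "secondary",
#'   "chd_strict")} to run; \code{"none"} produces the AIC table only.
#' @param p_keep,approx_level Passed to [build_interaction_model()].
#' @return Object of class \code{"ncc_analysis"}: \code{aic_table},
#'   \code{best}, \code{worst}, per-analysis [build_interaction_model()]
#'   results, a Table-2-style \code{report} data frame, the matched
#'   \code{sets}, cohort counts, and a run \code{manifest}.
#' @export
run_analysis <- function(population = NULL, config = NULL,
                         profiles = c("hypertension", "chd", "previous_mi",
                                      "aspirin_30d"),
                         ratio = 10, seed = NULL,
                         analyses = c("primary", "secondary", "chd_strict"),
                         p_keep = 0.2, approx_level = 0.8) {
  if (is.null(population)) {
    if (is.null(config)) .stopf("supply `population` or `config`")
    population <- simulate_outcomes(generate_population(config))
  }
  cfg <- population$config
  seed <- seed %||% (if (!is.null(cfg)) cfg$seed + 4L else 1L)
  study_start <- if (!is.null(cfg)) cfg$study_start else
    min(population$persons$coverage_start)
  study_end <- if (!is.null(cfg)) cfg$study_end else
    max(population$persons$coverage_end)

  coh <- assemble_cohort(population$persons, population$dispensings,
                         population$hospitalizations, study_start,
                         study_end)
  if (!nrow(coh$cohort)) .stopf("empty cohort")
  sets <- sample_controls(coh$cohort, ratio = ratio, seed = seed)
  if (!nrow(sets)) .stopf("no matched sets (no qualifying cases)")

  params <- parametrizations()
  # covariates do not depend on the parametrization: compute once
  ctx <- .member_context(sets, coh$cohort, population$persons,
                         population$dispensings,
                         population$hospitalizations)
  id_cols <- data.frame(set_id = sets$set_id, case = sets$case,
                        person_id = sets$person_id)
  covs_broad <- .covariate_columns(sets, ctx, "broad")
  datasets <- lapply(params, function(p) {
    out <- cbind(id_cols, .exposure_columns(sets, ctx, p), covs_broad)
    rownames(out) <- NULL
    out
  })
  base <- lapply(names(params), function(nm) .fit_base(datasets[[nm]]))
  names(base) <- names(params)
  fits <- lapply(base, `[[`, "fit")
  aic_table <- data.frame(
    model = names(params),
    current_as = vapply(params, `[[`, character(1), "current_as"),
    current_window = vapply(params, `[[`, character(1), "current_window"),
    k = vapply(fits, `[[`, numeric(1), "n_par"),
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    aic = vapply(fits, `[[`, numeric(1), "aic"),
    converged = vapply(fits, `[[`, logical(1), "converged"))
  ord <- order(aic_table$aic, aic_table$k)
  aic_table$rank <- match(seq_len(nrow(aic_table)), ord)
  best <- aic_table$model[ord[1]]
  worst <- aic_table$model[ord[nrow(aic_table)]]

  out <- list(aic_table = aic_table[order(aic_table$rank), ], best = best,
              worst = worst, sets = sets, cohort = coh$cohort,
              n_cohort = nrow(coh$cohort),
              n_excluded = nrow(coh$exclusions),
              exclusions = coh$exclusions)
  out$dropped_cases <- attr(sets, "dropped")
  if (identical(analyses, "none") || !length(analyses)) {
    out$manifest <- .run_manifest(cfg, seed, ratio, best, worst, analyses)
    return(structure(out, class = "ncc_analysis"))
  }
  analyses <- match.arg(analyses, several.ok = TRUE)

  mk_pairs <- function(data, p) {
    common <- setdiff(nsaid_groups(), "other_nsaid")
    grid <- expand.grid(nsaid = common, profile = profiles,
                        stringsAsFactors = FALSE)
    grid$main <- paste0(grid$nsaid, "_current")
    grid$scale10 <- 1
    if (p$current_as == "daily_dose") {
      for (i in seq_len(nrow(grid))) {
        doses <- data[[grid$main[i]]]
        doses <- doses[doses > 0]
        grid$scale10[i] <- if (length(doses))
          as.numeric(names(sort(table(doses), decreasing = TRUE))[1]) else 1
      }
    }
    grid$label <- paste(grid$nsaid, grid$profile, sep = ":")
    grid$nsaid <- paste0(grid$nsaid, "_current_bin")
    ok <- vapply(seq_len(nrow(grid)), function(i) {
      grid$main[i] %in% names(data) && grid$profile[i] %in% names(data) &&
        stats::var(data[[grid$main[i]]]) > 0 &&
        stats::var(data[[grid$profile[i]]]) > 0
    }, logical(1))
    grid[ok, , drop = FALSE]
  }

  run_one <- function(nm, chd_definition) {
    p <- params[[nm]]
    if (chd_definition == "broad") {
      data <- datasets[[nm]]
      f <- base[[nm]]$formula
    } else {
      data <- cbind(id_cols, .exposure_columns(sets, ctx, p),
                    .covariate_columns(sets, ctx, "strict"))
      rownames(data) <- NULL
      f <- .fit_base(data)$formula
    }
    pairs <- mk_pairs(data, p)
    build_interaction_model(data, f, pairs, p_keep = p_keep,
                            approx_level = approx_level)
  }
  if ("primary" %in% analyses) out$primary <- run_one(best, "broad")
  if ("secondary" %in% analyses) out$secondary <- run_one(worst, "broad")
  if ("chd_strict" %in% analyses) out$chd_strict <- run_one(best, "strict")

  rep_rows <- list()
  for (an in intersect(c("primary", "secondary", "chd_strict"),
                       names(out))) {
    im <- out[[an]]
    if (is.null(im$stage1)) next
    s1 <- im$stage1
    s1$analysis <- an
    s1$in_best_model <- s1$pair %in% im$retained
    for (lb in names(im$reri)) {
      r <- im$reri[[lb]]
      sel <- s1$pair == lb
      s1$reri[sel] <- r$reri; s1$lo[sel] <- r$ci[1]; s1$hi[sel] <- r$ci[2]
      s1$mult[sel] <- r$multiplicative
      s1$mult_lo[sel] <- r$multiplicative_ci[1]
      s1$mult_hi[sel] <- r$multiplicative_ci[2]
      s1$classification[sel] <- r$classification
    }
    rep_rows[[an]] <- s1
  }
  out$report <- do.call(rbind, rep_rows)
  rownames(out$report) <- NULL
  out$manifest <- .run_manifest(cfg, seed, ratio, best, worst, analyses)
  structure(out, class = "ncc_analysis")
}

# base-model fit with a convergence ladder: desk-scale synthetic datasets
# can put rare columns into quasi-separation, so the informativeness filter
# is tightened stepwise and, as a last resort, separating columns dropped
.fit_base <- function(data, thresholds = c(8, 15, 25, 40)) {
  last <- NULL
  for (th in thresholds) {
    f <- base_model_formula(data, min_informative_sets = th)
    fit <- suppressWarnings(cond_logit(f, data))
    last <- list(fit = fit, formula = f)
    if (fit$converged) return(last)
  }
  bad <- names(last$fit$coefficients)[abs(last$fit$coefficients) > 5]
  keep <- setdiff(attr(stats::terms(last$formula), "term.labels"), bad)
  if (length(bad) && length(keep)) {
    f2 <- stats::reformulate(keep, response = "case")
    fit2 <- suppressWarnings(cond_logit(f2, data))
    if (fit2$converged) return(list(fit = fit2, formula = f2))
  }
  last
}

.run_manifest <- function(cfg, seed, ratio, best, worst, analyses) {
  list(package = "nccreri",
       version = as.character(utils::packageVersion("nccreri")),
       r_version = paste(R.version$major, R.version$minor, sep = "."),
       sampling_seed = seed, ratio = ratio,
       config_seed = if (!is.null(cfg)) cfg$seed else NA,
       best_parametrization = best, worst_parametrization = worst,
       analyses = as.list(analyses))
}

#' @export
print.ncc_analysis <- function(x, ...) {
  cat("Nested case-control interaction analysis\n")
  cat("Cohort:", x$n_cohort, "members (", x$n_excluded, "excluded );",
      length(unique(x$sets$set_id)), "matched sets\n")
  cat("Base-model AIC ranking (best ->", x$best, ", worst ->", x$worst,
      "):\n")
  print(x$aic_table[, c("model", "k", "aic", "rank")], row.names = FALSE)
  if (!is.null(x$report)) {
    cat("\nInteraction findings (pairs in AIC-selected models):\n")
    sel <- x$report[x$report$in_best_model, c("analysis", "pair", "reri",
                                              "lo", "hi",
                                              "classification")]
    if (nrow(sel)) print(sel, row.names = FALSE, digits = 3)
    else cat("  none retained\n")
  }
  invisible(x)
}

#' Write the analysis report bundle
#'
#' Writes \code{aic_table.csv}, \code{cohort.csv}, \code{exclusions.csv},
#' \code{sets.csv}, \code{table2_report.csv}, \code{decision_log.jsonl}
#' (one JSON record per model-building decision) and \code{manifest.json}
#' to a directory. Outputs are byte-identical for identical inputs and
#' seed.
#'
#' @param result An [run_analysis()] result.
#' @param dir Output directory.
#' @return \code{dir}, invisibly.
#' @export
write_analysis <- function(result, dir) {
  stopifnot(inherits(result, "ncc_analysis"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$aic_table, file.path(dir, "aic_table.csv"),
                   row.names = FALSE)
  utils::write.csv(result$cohort, file.path(dir, "cohort.csv"),
                   row.names = FALSE)
  utils::write.csv(result$exclusions, file.path(dir, "exclusions.csv"),
                   row.names = FALSE)
  sets_out <- data.frame(result$sets,
                         role = ifelse(result$sets$case == 1, "case",
                                       "control"))
  utils::write.csv(sets_out, file.path(dir, "sets.csv"),
                   row.names = FALSE)
  if (!is.null(result$report))
    utils::write.csv(result$report, file.path(dir, "table2_report.csv"),
                     row.names = FALSE)
  logs <- list()
  for (an in intersect(c("primary", "secondary", "chd_strict"),
                       names(result))) {
    lg <- result[[an]]$log
    if (is.null(lg) || !nrow(lg)) next
    lg$analysis <- an
    logs[[an]] <- lg
  }
  con <- file(file.path(dir, "decision_log.jsonl"), "w")
  on.exit(close(con))
  for (lg in logs)
    for (i in seq_len(nrow(lg)))
      writeLines(jsonlite::toJSON(as.list(lg[i, ]), auto_unbox = TRUE,
                                  digits = NA, na = "null"), con)
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
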