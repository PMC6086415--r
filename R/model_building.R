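#' Staged product-term model building for additive interaction
#'
#' Implements the product-term selection procedure around a base model
#' without interactions. Stage 1 tests each candidate drug-by-profile
#' product term added alone to the base model and all terms added jointly;
#' a term is kept when (i) its Wald p-value (individually or jointly) is at
#' most \code{p_keep}, or (ii) it deviates or approximately deviates from
#' exact multiplicativity or exact additivity, operationalised as the
#' \code{approx_level} confidence interval for RERI excluding 0 or for
#' exp(beta11) excluding 1. Stage 2 prunes kept terms whose
#' \code{conf_level} intervals are compatible with both exact additivity
#' (RERI CI spans 0) and exact multiplicativity (exp(beta11) CI spans 1).
#' Stage 3 fits the base model and candidate models over subsets of the
#' remaining terms (all subsets when few, otherwise the full set and
#' leave-one-out subsets) and selects the minimum-AIC model, breaking ties
#' in favour of fewer parameters. Every test and verdict is recorded in a
#' decision log.
#'
#' @param data Analysis data frame (one row per set member).
#' @param base_formula Formula of the base model (no product terms).
#' @param pairs Data frame describing candidate pairs with columns
#'   \code{nsaid} (binary current-use column used to form the product),
#'   \code{profile} (profile column), and optionally \code{main}
#'   (main-effect coefficient for RERI, default \code{nsaid}) and
#'   \code{scale10} (reference dose multiplier, default 1).
#' @param set Set-id column name.
#' @param p_keep Wald retention threshold (0.2 in the staged procedure).
#' @param approx_level Confidence level defining "approximately deviates".
#' @param conf_level Level for reported RERI intervals and stage-2 pruning.
#' @param max_enumerate Largest retained-set size for exhaustive subset
#'   enumeration in stage 3.
#' @return Object of class \code{"interaction_model"}: \code{base_fit},
#'   \code{final_fit}, \code{retained} (pair labels in the selected model),
#'   \code{reri} (list of [reri()] results from the final model),
#'   \code{stage1} (per-pair test summary), \code{candidates} (AIC table of
#'   stage-3 models), \code{log} (decision-log data frame),
#'   \code{joint_test} (all-products Wald test).
#' @export
build_interaction_model <- function(data, base_formula, pairs,
                                    set = "set_id", p_keep = 0.2,
                                    approx_level = 0.8, conf_level = 0.95,
                                    max_enumerate = 4) {
  base_fit <- cond_logit(base_formula, data, set = set)
  if (!base_fit$converged) .stopf("base model did not converge")
  if (is.null(pairs) || !nrow(pairs)) {
    return(structure(list(base_fit = base_fit, final_fit = base_fit,
                          retained = character(), reri = list(),
                          stage1 = NULL, candidates = NULL,
                          log = data.frame(), joint_test = NULL),
                     class = "interaction_model"))
  }
  pairs <- as.data.frame(pairs)
  if (is.null(pairs$main)) pairs$main <- pairs$nsaid
  if (is.null(pairs$scale10)) pairs$scale10 <- 1
  pairs$term <- paste0("px_", pairs$nsaid, "_", pairs$profile)
  if (is.null(pairs$label))
    pairs$label <- paste(pairs$nsaid, pairs$profile, sep = ":")

  logs <- list()
  note <- function(...) logs[[length(logs) + 1L]] <<- data.frame(...)

  d <- data
  usable <- logical(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    prod_col <- d[[pairs$nsaid[i]]] * d[[pairs$profile[i]]]
    d[[pairs$term[i]]] <- as.numeric(prod_col > 0)
    sid <- d[[set]]
    varies <- any(stats::ave(d[[pairs$term[i]]], sid, FUN = function(v)
      max(v) - min(v)) > 0)
    usable[i] <- varies
    if (!varies)
      note(stage = 1L, pair = pairs$label[i], test = "screen",
           p = NA_real_, reri = NA_real_, lo = NA_real_, hi = NA_real_,
           verdict = "skipped_degenerate")
  }

  fit_with <- function(terms) {
    f <- stats::update(base_formula,
                       paste("~ . +", paste(terms, collapse = " + ")))
    tryCatch(suppressWarnings(cond_logit(f, d, set = set)),
             error = function(e) NULL)
  }

  keep <- logical(nrow(pairs))
  stage1 <- vector("list", nrow(pairs))
  screen_one <- function(fit, i, test_label) {
    tm <- pairs$term[i]
    if (is.null(fit) || !fit$converged || !tm %in% names(fit$coefficients))
      return(NULL)
    w <- tryCatch(wald_test(fit, tm), error = function(e) NULL)
    if (is.null(w)) return(NULL)
    r_main <- reri(fit, pairs$main[i], pairs$profile[i], tm,
                   conf_level = conf_level, scale10 = pairs$scale10[i])
    r_apx <- reri(fit, pairs$main[i], pairs$profile[i], tm,
                  conf_level = approx_level, scale10 = pairs$scale10[i])
    deviates <- (all(is.finite(r_apx$ci)) &&
                   (r_apx$ci[1] > 0 || r_apx$ci[2] < 0)) ||
      (all(is.finite(r_apx$multiplicative_ci)) &&
         (r_apx$multiplicative_ci[1] > 1 || r_apx$multiplicative_ci[2] < 1))
    kept <- w$p_value <= p_keep || deviates
    note(stage = 1L, pair = pairs$label[i], test = test_label,
         p = w$p_value, reri = r_main$reri, lo = r_main$ci[1],
         hi = r_main$ci[2],
         verdict = if (kept) "kept" else "not_kept")
    list(kept = kept, p = w$p_value, r = r_main)
  }

  for (i in which(usable)) {
    res <- screen_one(fit_with(pairs$term[i]), i, "individual")
    if (is.null(res)) {
      note(stage = 1L, pair = pairs$label[i], test = "individual",
           p = NA_real_, reri = NA_real_, lo = NA_real_, hi = NA_real_,
           verdict = "skipped_nonconvergence")
      usable[i] <- FALSE
      next
    }
    keep[i] <- res$kept
    stage1[[i]] <- data.frame(pair = pairs$label[i], p_individual = res$p,
                              reri = res$r$reri, lo = res$r$ci[1],
                              hi = res$r$ci[2],
                              mult = res$r$multiplicative,
                              mult_lo = res$r$multiplicative_ci[1],
                              mult_hi = res$r$multiplicative_ci[2],
                              classification = res$r$classification)
  }

  joint_test <- NULL
  if (sum(usable) > 1) {
    jfit <- fit_with(pairs$term[usable])
    if (!is.null(jfit) && jfit$converged) {
      present <- intersect(pairs$term[usable], names(jfit$coefficients))
      joint_test <- tryCatch(wald_test(jfit, present),
                             error = function(e) NULL)
      if (!is.null(joint_test))
        note(stage = 1L, pair = "all", test = "joint_all_terms",
             p = joint_test$p_value, reri = NA_real_, lo = NA_real_,
             hi = NA_real_, verdict = "recorded")
      for (i in which(usable)) {
        res <- screen_one(jfit, i, "joint")
        if (!is.null(res)) keep[i] <- keep[i] || res$kept
      }
    }
  }

  # stage 2: prune terms compatible with both exact additivity and exact
  # multiplicativity at the reporting level
  for (i in which(keep)) {
    s1 <- stage1[[i]]
    both <- !is.null(s1) && is.finite(s1$lo) && is.finite(s1$hi) &&
      s1$lo <= 0 && s1$hi >= 0 && s1$mult_lo <= 1 && s1$mult_hi >= 1
    if (both) {
      keep[i] <- FALSE
      note(stage = 2L, pair = pairs$label[i], test = "prune",
           p = NA_real_, reri = s1$reri, lo = s1$lo, hi = s1$hi,
           verdict = "pruned_additive_and_multiplicative")
    }
  }

  retained_idx <- which(keep)
  subsets <- list(integer(0))
  if (length(retained_idx)) {
    if (length(retained_idx) <= max_enumerate) {
      for (m in seq_along(retained_idx))
        subsets <- c(subsets, lapply(
          asplit(utils::combn(retained_idx, m), 2), as.integer))
    } else {
      subsets <- c(subsets, list(retained_idx),
                   lapply(seq_along(retained_idx),
                          function(j) retained_idx[-j]))
    }
  }
  cand <- lapply(subsets, function(ix) {
    fit <- if (!length(ix)) base_fit else fit_with(pairs$term[ix])
    if (is.null(fit) || !fit$converged) {
      note(stage = 3L, pair = paste(pairs$label[ix], collapse = "+"),
           test = "aic", p = NA_real_, reri = NA_real_, lo = NA_real_,
           hi = NA_real_, verdict = "skipped_nonconvergence")
      return(NULL)
    }
    list(ix = ix, fit = fit, aic = fit$aic, k = fit$n_par)
  })
  cand <- cand[!vapply(cand, is.null, logical(1))]
  aics <- vapply(cand, `[[`, numeric(1), "aic")
  ks <- vapply(cand, `[[`, numeric(1), "k")
  best <- order(aics, ks)[1L]
  final_fit <- cand[[best]]$fit
  final_ix <- cand[[best]]$ix
  note(stage = 3L,
       pair = if (length(final_ix))
         paste(pairs$label[final_ix], collapse = "+") else "(base)",
       test = "aic", p = NA_real_, reri = NA_real_, lo = NA_real_,
       hi = NA_real_, verdict = "selected")

  final_reri <- list()
  for (i in final_ix) {
    final_reri[[pairs$label[i]]] <-
      reri(final_fit, pairs$main[i], pairs$profile[i], pairs$term[i],
           conf_level = conf_level, scale10 = pairs$scale10[i])
  }
  stage1_df <- do.call(rbind, stage1[!vapply(stage1, is.null, logical(1))])
  cand_df <- data.frame(
    model = vapply(cand, function(cc) if (length(cc$ix))
      paste(pairs$label[cc$ix], collapse = "+") else "(base)",
      character(1)),
    k = ks, aic = aics)
  structure(list(base_fit = base_fit, final_fit = final_fit,
                 retained = pairs$label[final_ix], reri = final_reri,
                 stage1 = stage1_df, candidates = cand_df,
                 log = do.call(rbind, logs), joint_test = joint_test,
                 pairs = pairs, data = d, set = set),
            class = "interaction_model")
}

#' @export
print.interaction_model <- function(x, ...) {
  cat("Interaction model building:", nrow(x$pairs %||% data.frame()),
      "candidate pairs;", length(x$retained), "in selected model\n")
  if (!is.null(x$candidates)) {
    cat("AIC-selected model:",
        x$candidates$model[which.min(x$candidates$aic)], "\n")
  }
  for (r in x$reri) print(r)
  invisible(x)
}
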