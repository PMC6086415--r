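#' Relative excess risk due to interaction from regression coefficients
#'
#' For two exposures with main-effect coefficients beta10 (drug), beta01
#' (profile) and product-term coefficient beta11 on the log-odds scale,
#' RERI_OR = OR11 - OR10 - OR01 + 1
#'         = exp(beta10 + beta01 + beta11) - exp(beta10) - exp(beta01) + 1.
#' It is 0 under exactly additive joint effects; the product-term
#' coefficient beta11 is 0 under exact multiplicativity. The confidence
#' interval is obtained by the delta method with gradient
#' (OR11 - OR10, OR11 - OR01, OR11) over the coefficients' 3x3 covariance
#' block.
#'
#' When current drug exposure is modelled as a continuous daily dose, the
#' drug's log-odds at a reference dose d* is d* times the dose coefficient;
#' supply \code{scale10 = d*} to evaluate RERI at that dose (the first
#' gradient component is then scaled by d*).
#'
#' @param beta10,beta01,beta11 Coefficients on the log-odds-ratio scale.
#' @param vcov Optional 3x3 covariance matrix of
#'   (beta10, beta01, beta11); without it only the point estimates are
#'   returned.
#' @param conf_level Confidence level (normal quantile; 1.96 at 95%).
#' @param scale10 Multiplier applied to beta10 (reference dose for
#'   dose-parametrized models; 1 for binary exposure).
#' @param pair Optional length-2 character label (drug, profile).
#' @return Object of class \code{"reri"}: \code{reri}, \code{se}, \code{ci}
#'   (at \code{conf_level}), \code{multiplicative} = exp(beta11) with its
#'   CI, and \code{classification} from [classify_joint_effects()].
#' @examples
#' reri_estimate(log(2), log(3), log(4 / 6))  # exactly additive: RERI = 0
#' reri_estimate(log(2), log(3), 0)           # exactly multiplicative: 2
#' @export
reri_estimate <- function(beta10, beta01, beta11, vcov = NULL,
                          conf_level = 0.95, scale10 = 1, pair = NULL) {
  b10 <- scale10 * beta10
  or10 <- exp(b10); or01 <- exp(beta01); or11 <- exp(b10 + beta01 + beta11)
  est <- or11 - or10 - or01 + 1
  out <- list(pair = pair, beta10 = beta10, beta01 = beta01,
              beta11 = beta11, scale10 = scale10,
              or10 = or10, or01 = or01, or11 = or11, reri = est,
              conf_level = conf_level,
              multiplicative = exp(beta11))
  if (!is.null(vcov)) {
    stopifnot(is.matrix(vcov), all(dim(vcov) == c(3, 3)))
    g <- c(scale10 * (or11 - or10), or11 - or01, or11)
    v <- drop(t(g) %*% vcov %*% g)
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    out$se <- sqrt(max(v, 0))
    out$ci <- c(est - z * out$se, est + z * out$se)
    se11 <- sqrt(vcov[3, 3])
    out$multiplicative_ci <- exp(beta11 + c(-1, 1) * z * se11)
    out$classification <- classify_joint_effects(out$ci[1], out$ci[2])
  } else {
    out$se <- NA_real_; out$ci <- c(NA_real_, NA_real_)
    out$multiplicative_ci <- c(NA_real_, NA_real_)
    out$classification <- "inconclusive"
  }
  structure(out, class = "reri")
}

#' RERI for a drug-profile pair from a fitted model
#'
#' Extracts the pair's main-effect and product-term coefficients and their
#' covariance block from a [cond_logit()] fit and delegates to
#' [reri_estimate()].
#'
#' @param fit A converged [cond_logit()] fit.
#' @param nsaid,profile,product Coefficient names of the drug main effect,
#'   the profile main effect, and their product term.
#' @param conf_level Confidence level.
#' @param scale10 Reference dose multiplier for dose-parametrized drug
#'   terms (1 for binary terms).
#' @return Object of class \code{"reri"}.
#' @export
reri <- function(fit, nsaid, profile, product, conf_level = 0.95,
                 scale10 = 1) {
  stopifnot(inherits(fit, "cond_logit"))
  nm <- c(nsaid, profile, product)
  miss <- setdiff(nm, names(fit$coefficients))
  if (length(miss))
    .stopf("fit does not contain term(s): %s", paste(miss, collapse = ", "))
  b <- unname(fit$coefficients[nm])
  reri_estimate(b[1], b[2], b[3], vcov = fit$vcov[nm, nm],
                conf_level = conf_level, scale10 = scale10,
                pair = c(nsaid, profile))
}

#' Classify joint effects from a RERI confidence interval
#'
#' An upper confidence bound below 0 indicates sub-additive joint effects; a
#' lower bound above 0 indicates super-additive joint effects; an interval
#' containing 0 is compatible with exact additivity; a degenerate or
#' non-finite interval is inconclusive.
#'
#' @param lower,upper RERI confidence bounds.
#' @return One of \code{"sub_additive"}, \code{"super_additive"},
#'   \code{"exact_additive_compatible"}, \code{"inconclusive"}.
#' @export
classify_joint_effects <- function(lower, upper) {
  if (!is.finite(lower) || !is.finite(upper) || lower > upper)
    return("inconclusive")
  if (upper < 0) return("sub_additive")
  if (lower > 0) return("super_additive")
  "exact_additive_compatible"
}

#' @export
print.reri <- function(x, digits = 3, ...) {
  if (!is.null(x$pair))
    cat("Pair:", paste(x$pair, collapse = " x "), "\n")
  cat(sprintf("RERI = %.*f (%g%% CI %.*f, %.*f) -> %s\n", digits, x$reri,
              100 * x$conf_level, digits, x$ci[1], digits, x$ci[2],
              x$classification))
  cat(sprintf("multiplicative measure exp(beta11) = %.*f (%.*f, %.*f)\n",
              digits, x$multiplicative, digits, x$multiplicative_ci[1],
              digits, x$multiplicative_ci[2]))
  invisible(x)
}
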