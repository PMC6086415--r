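#' Conditional log-likelihood for matched case-control sets
#'
#' The conditional likelihood of a 1:m matched set is the probability that
#' the case, among the set's members, is the one with the event:
#' exp(x_case beta) / sum_j exp(x_j beta). The log-likelihood sums
#' log of that over sets, evaluated with log-sum-exp stabilisation so it is
#' finite for any finite inputs. Covariates constant within a set contribute
#' nothing.
#'
#' @param beta Coefficient vector (log-odds-ratio scale).
#' @param x Design matrix (rows = set members, no intercept).
#' @param case 0/1 indicator, exactly one 1 per set.
#' @param set Set identifier, one per row.
#' @return Log-likelihood value.
#' @export
cond_logit_loglik <- function(beta, x, case, set) {
  if (length(beta) != ncol(x))
    .stopf("length(beta) == %d but ncol(x) == %d", length(beta), ncol(x))
  eta <- drop(x %*% beta)
  f <- factor(set)
  m <- tapply(eta, f, max)[f]
  denom <- tapply(exp(eta - m), f, sum)
  sum(eta[case == 1]) - sum(as.numeric(m[!duplicated(f)]) + log(denom))
}

.cl_prepare <- function(x, case, set) {
  o <- order(set)
  x <- x[o, , drop = FALSE]; case <- case[o]; set <- set[o]
  sid <- match(set, unique(set))
  per <- tabulate(sid)
  if (any(tapply(case, sid, sum) != 1))
    .stopf("every matched set must contain exactly one case")
  list(x = x, case = case, sid = sid, n_sets = max(sid), per = per)
}

.cl_ll_grad_hess <- function(beta, p, want_hess = TRUE) {
  eta <- drop(p$x %*% beta)
  msets <- as.vector(tapply(eta, p$sid, max))
  e <- exp(eta - msets[p$sid])
  denom <- drop(rowsum(e, p$sid))
  w <- e / denom[p$sid]
  ll <- sum(eta[p$case == 1]) - sum(msets + log(denom))
  g <- colSums(p$x * (p$case - w))
  out <- list(ll = ll, grad = g)
  if (want_hess) {
    xbar <- rowsum(p$x * w, p$sid)
    info <- crossprod(p$x * sqrt(w)) - crossprod(xbar)
    out$info <- info
  }
  out
}

#' Conditional logistic regression for individually matched sets
#'
#' Fits the conditional likelihood of 1:m matched case-control sets
#' (variable m supported) by Newton-Raphson with analytic gradient and
#' Hessian and step-halving whenever a step decreases the likelihood.
#' Convergence is declared when the gradient max-norm falls below
#' \code{tol}; the covariance matrix is the inverse observed information at
#' the optimum. Diverging coefficients (|beta| > 15), the signature of
#' complete or quasi-separation, are flagged, never silently returned as
#' converged. Design columns with no variation within any set carry no
#' information under the conditional likelihood and are dropped with a
#' warning.
#'
#' @param formula Model formula, e.g. \code{case ~ exposure + confounder};
#'   no intercept is fitted (set-level intercepts cancel from the
#'   conditional likelihood).
#' @param data Data frame containing the response, covariates and set id.
#' @param set Name of the set-identifier column (default \code{"set_id"}).
#' @param start Optional starting coefficients (default all zero).
#' @param tol Gradient max-norm convergence tolerance.
#' @param max_iter Maximum Newton iterations.
#' @return Object of class \code{"cond_logit"}: coefficients, \code{vcov},
#'   \code{loglik}, \code{loglik_null}, \code{aic}, \code{n_sets},
#'   \code{converged}, \code{n_iter}, \code{gradient}, \code{separation},
#'   \code{dropped} (names of degenerate columns removed).
#' @examples
#' d <- data.frame(set_id = rep(1:30, each = 2),
#'                 case = rep(c(1, 0), 30),
#'                 x = rbinom(60, 1, 0.4))
#' fit <- cond_logit(case ~ x, d)
#' coef(fit)
#' @export
cond_logit <- function(formula, data, set = "set_id", start = NULL,
                       tol = 1e-8, max_iter = 100) {
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  x <- stats::model.matrix(stats::terms(formula, data = data), mf)
  x <- x[, colnames(x) != "(Intercept)", drop = FALSE]
  if (!set %in% names(data)) .stopf("set column `%s` not found", set)
  p <- .cl_prepare(x, y, data[[set]])

  # columns constant within every set are inestimable under the
  # conditional likelihood
  ctr <- p$x - rowsum(p$x, p$sid)[p$sid, , drop = FALSE] / p$per[p$sid]
  degen <- apply(abs(ctr), 2, max) < 1e-12
  dropped <- colnames(p$x)[degen]
  if (any(degen)) {
    warning("dropping column(s) with no within-set variation: ",
            paste(dropped, collapse = ", "), call. = FALSE)
    p$x <- p$x[, !degen, drop = FALSE]
  }
  k <- ncol(p$x)
  beta <- if (is.null(start)) numeric(k) else {
    stopifnot(length(start) == k); as.numeric(start)
  }
  ll_null <- -sum(log(p$per[!duplicated(p$sid)]))

  cur <- .cl_ll_grad_hess(beta, p)
  converged <- FALSE; separation <- FALSE; iter <- 0L
  while (iter < max_iter) {
    if (max(abs(cur$grad)) < tol) { converged <- TRUE; break }
    iter <- iter + 1L
    step <- tryCatch(solve(cur$info, cur$grad), error = function(e) NULL)
    if (is.null(step)) break
    lambda <- 1
    repeat {
      cand <- beta + lambda * step
      new <- .cl_ll_grad_hess(cand, p)
      if (new$ll >= cur$ll - 1e-12 || lambda < 1e-6) break
      lambda <- lambda / 2
    }
    beta <- cand; cur <- new
    if (max(abs(beta)) > 15) { separation <- TRUE; break }
  }
  if (max(abs(cur$grad)) < tol && !separation) converged <- TRUE
  if (separation)
    warning("separation suspected: |beta| exceeded 15; fit flagged",
            call. = FALSE)
  if (!converged && !separation)
    warning("Newton-Raphson did not converge in ", max_iter, " iterations",
            call. = FALSE)
  vc <- tryCatch({
    v <- solve(cur$info)
    (v + t(v)) / 2
  }, error = function(e) matrix(NA_real_, k, k))
  dimnames(vc) <- list(colnames(p$x), colnames(p$x))
  names(beta) <- colnames(p$x)

  structure(list(coefficients = beta, vcov = vc, loglik = cur$ll,
                 loglik_null = ll_null, aic = 2 * k - 2 * cur$ll,
                 n_sets = p$n_sets, n_obs = nrow(p$x), n_par = k,
                 converged = converged, separation = separation,
                 n_iter = iter, gradient = cur$grad, dropped = dropped,
                 formula = formula, set = set, call = match.call()),
            class = "cond_logit")
}

#' @export
coef.cond_logit <- function(object, ...) object$coefficients

#' @export
vcov.cond_logit <- function(object, ...) object$vcov

#' @export
logLik.cond_logit <- function(object, ...) {
  structure(object$loglik, df = object$n_par, nobs = object$n_sets,
            class = "logLik")
}

#' Akaike information criterion of a conditional logistic fit
#'
#' \code{2k - 2 log L} with k the number of fitted coefficients.
#' @param fit A [cond_logit()] fit.
#' @return AIC value.
#' @export
aic <- function(fit) {
  stopifnot(inherits(fit, "cond_logit"))
  fit$aic
}

#' @export
print.cond_logit <- function(x, digits = 4, ...) {
  cat("Conditional logistic regression (", x$n_sets, " matched sets, ",
      x$n_obs, " subjects)\n", sep = "")
  print(round(x$coefficients, digits))
  cat("logLik:", format(x$loglik, digits = digits),
      "  AIC:", format(x$aic, digits = digits),
      if (!x$converged) " [NOT CONVERGED]" else "", "\n")
  invisible(x)
}

#' @export
summary.cond_logit <- function(object, conf_level = 0.95, ...) {
  se <- sqrt(diag(object$vcov))
  z <- object$coefficients / se
  q <- stats::qnorm(1 - (1 - conf_level) / 2)
  tab <- cbind(coef = object$coefficients, se = se,
               OR = exp(object$coefficients),
               lower = exp(object$coefficients - q * se),
               upper = exp(object$coefficients + q * se),
               z = z, p = 2 * stats::pnorm(-abs(z)))
  structure(list(coefficients = tab, loglik = object$loglik,
                 aic = object$aic, n_sets = object$n_sets,
                 converged = object$converged,
                 separation = object$separation,
                 conf_level = conf_level),
            class = "summary.cond_logit")
}

#' @export
print.summary.cond_logit <- function(x, digits = 4, ...) {
  cat("Conditional logistic regression,", x$n_sets, "matched sets\n")
  stats::printCoefmat(x$coefficients, digits = digits, P.values = TRUE,
                      has.Pvalue = TRUE)
  cat("logLik:", format(x$loglik, digits = digits),
      "  AIC:", format(x$aic, digits = digits), "\n")
  if (x$separation) cat("Warning: separation suspected\n")
  else if (!x$converged) cat("Warning: not converged\n")
  invisible(x)
}

#' @export
confint.cond_logit <- function(object, parm, level = 0.95, ...) {
  se <- sqrt(diag(object$vcov))
  q <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(object$coefficients - q * se, object$coefficients + q * se)
  colnames(ci) <- paste0(100 * c((1 - level) / 2, 1 - (1 - level) / 2), " %")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' Predict from a conditional logistic fit
#'
#' @param object A [cond_logit()] fit.
#' @param newdata Data frame with the model covariates and the set column.
#' @param type \code{"lp"} for linear predictors or \code{"prob"} for
#'   within-set case probabilities (softmax of the linear predictor over set
#'   members).
#' @param ... Unused.
#' @return Numeric vector aligned with rows of \code{newdata}.
#' @export
predict.cond_logit <- function(object, newdata, type = c("lp", "prob"),
                               ...) {
  type <- match.arg(type)
  tt <- stats::delete.response(stats::terms(object$formula, data = newdata))
  x <- stats::model.matrix(tt, stats::model.frame(tt, newdata))
  x <- x[, colnames(x) != "(Intercept)", drop = FALSE]
  x <- x[, names(object$coefficients), drop = FALSE]
  eta <- unname(drop(x %*% object$coefficients))
  if (type == "lp") return(eta)
  sid <- newdata[[object$set]]
  f <- factor(sid, levels = unique(sid))
  m <- as.vector(tapply(eta, f, max))[as.integer(f)]
  e <- exp(eta - m)
  as.vector(e / drop(rowsum(e, as.integer(f)))[as.integer(f)])
}

#' Wald test of one or several coefficients
#'
#' Computes beta' V^-1 beta for the selected coefficients against a
#' chi-square with as many degrees of freedom as coefficients tested; for a
#' single term this equals (beta/se)^2.
#'
#' @param fit A [cond_logit()] fit.
#' @param terms Coefficient names or indices.
#' @return List with \code{statistic}, \code{df}, \code{p_value}.
#' @export
wald_test <- function(fit, terms) {
  stopifnot(inherits(fit, "cond_logit"))
  b <- fit$coefficients[terms]
  if (any(is.na(b))) .stopf("unknown term(s): %s",
                            paste(terms[is.na(b)], collapse = ", "))
  V <- fit$vcov[terms, terms, drop = FALSE]
  inv <- tryCatch(solve(V), error = function(e) NULL)
  if (is.null(inv) || any(!is.finite(V)))
    .stopf("singular covariance submatrix for terms: %s",
           paste(names(b), collapse = ", "))
  stat <- drop(t(b) %*% inv %*% b)
  list(statistic = stat, df = length(b),
       p_value = stats::pchisq(stat, length(b), lower.tail = FALSE))
}
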