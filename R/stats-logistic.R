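#' Maximum-likelihood logistic regression via IRLS
#'
#' Fits a binary logistic regression by iteratively reweighted least squares
#' (Newton scoring on the log-likelihood). This is the regression kernel used
#' by every scan in the package; it is deliberately free of formula-interface
#' overhead so that tens of thousands of phenotype fits stay cheap.
#'
#' Convergence is declared when the maximum absolute score (gradient of the
#' log-likelihood) falls below `score_tol`. Perfect or quasi-complete
#' separation manifests as non-convergence within `max_iter` iterations; the
#' fit is then returned with `converged = FALSE` and callers are expected to
#' skip it (the scan functions do, with a log entry). Rank-deficient designs
#' are an error naming the collinear columns.
#'
#' @param design numeric matrix including an intercept column; column names
#'   are used in error messages and coefficient names.
#' @param outcome binary 0/1 vector, one element per design row.
#' @param max_iter maximum Newton iterations.
#' @param score_tol convergence tolerance on the maximum absolute score.
#' @return an object of class `ua_fit`: list with `coefficients`,
#'   `standard_errors`, `covariance`, `log_likelihood`, `p_values` (two-sided
#'   Wald), `converged`, `n_used`, `n_events`, `iterations`.
#' @examples
#' x <- cbind(intercept = 1, exposure = rep(0:1, each = 100))
#' y <- c(rbinom(100, 1, 0.2), rbinom(100, 1, 0.4))
#' fit <- fit_logistic(x, y)
#' coef(fit)
#' @export
fit_logistic <- function(design, outcome, max_iter = 50L, score_tol = 1e-8) {
  design <- as.matrix(design)
  storage.mode(design) <- "double"
  outcome <- as.numeric(outcome)
  if (nrow(design) != length(outcome)) {
    stop("design and outcome lengths differ")
  }
  keep <- stats::complete.cases(design) & !is.na(outcome)
  if (!all(keep)) {
    design <- design[keep, , drop = FALSE]
    outcome <- outcome[keep]
  }
  if (!all(outcome %in% c(0, 1))) stop("outcome must be coded 0/1")
  if (sum(outcome) == 0 || sum(outcome) == length(outcome)) {
    stop("outcome is constant; no events or all events")
  }
  if (is.null(colnames(design))) {
    colnames(design) <- paste0("x", seq_len(ncol(design)))
  }
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) {
    bad <- colnames(design)[qr_d$pivot[(qr_d$rank + 1L):ncol(design)]]
    stop("design is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }

  n <- nrow(design)
  p <- ncol(design)
  beta <- numeric(p)
  ll_old <- -Inf
  converged <- FALSE
  iters <- 0L
  info <- NULL

  loglik <- function(eta) {
    # numerically safe Bernoulli log-likelihood
    sum(outcome * eta - log1p(exp(pmin(eta, 500))))
  }

  for (it in seq_len(max_iter)) {
    iters <- it
    eta <- drop(design %*% beta)
    mu <- stats::plogis(eta)
    score <- drop(crossprod(design, outcome - mu))
    if (max(abs(score)) < score_tol) {
      converged <- TRUE
      break
    }
    w <- pmax(mu * (1 - mu), .Machine$double.eps)
    info <- crossprod(design * w, design)
    step <- tryCatch(solve(info, score), error = function(e) NULL)
    if (is.null(step)) break
    # step-halving keeps the likelihood monotone on hard designs
    ll_new <- loglik(drop(design %*% (beta + step)))
    half <- 0L
    while (ll_new < ll_old && half < 12L) {
      step <- step / 2
      ll_new <- loglik(drop(design %*% (beta + step)))
      half <- half + 1L
    }
    beta <- beta + step
    ll_old <- ll_new
  }

  # separation drives coefficients to +/-inf while the score still vanishes
  # numerically; a huge coefficient is the reliable symptom
  if (max(abs(beta)) > 15) converged <- FALSE
  eta <- drop(design %*% beta)
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), .Machine$double.eps)
  info <- crossprod(design * w, design)
  vcv <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(vcv) || any(!is.finite(diag(vcv))) || any(diag(vcv) <= 0)) {
    converged <- FALSE
    vcv <- matrix(NA_real_, p, p)
  }
  se <- sqrt(diag(vcv))
  z <- beta / se
  pv <- pmin(2 * stats::pnorm(-abs(z)), 1)
  names(beta) <- names(se) <- colnames(design)
  dimnames(vcv) <- list(colnames(design), colnames(design))

  structure(
    list(coefficients = beta,
         standard_errors = se,
         covariance = vcv,
         log_likelihood = loglik(eta),
         p_values = pv,
         converged = converged,
         n_used = n,
         n_events = sum(outcome),
         iterations = iters),
    class = "ua_fit")
}

#' Conditional (matched-set) logistic regression
#'
#' Maximizes the conditional likelihood for matched case-control data with
#' exactly one case per stratum: each stratum contributes
#' \eqn{\exp(x_{case}\beta) / \sum_j \exp(x_j\beta)} over its members. The
#' stratum nuisance intercepts cancel, so matched confounders need not be
#' modelled. Fitting is Newton-Raphson on the conditional log-likelihood with
#' step-halving.
#'
#' Strata without exactly one case, or with a single member, are dropped and
#' counted (`n_strata_dropped`). Strata in which no covariate varies are
#' uninformative; if every stratum is uninformative the fit errors.
#'
#' @param strata stratum labels (matched-set identifiers), one per row.
#' @param exposure numeric exposure vector (the coefficient of interest).
#' @param outcome binary 0/1 case indicator.
#' @param covariates optional numeric matrix of additional columns (no
#'   intercept; it is not identifiable conditionally).
#' @param max_iter,score_tol Newton controls as in [fit_logistic()].
#' @return a `ua_fit` object (log-likelihood is the conditional one); extra
#'   fields `n_strata_used`, `n_strata_dropped`.
#' @export
fit_conditional_logistic <- function(strata, exposure, outcome,
                                     covariates = NULL,
                                     max_iter = 50L, score_tol = 1e-8) {
  x <- cbind(exposure = as.numeric(exposure))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    storage.mode(covariates) <- "double"
    x <- cbind(x, covariates)
  }
  outcome <- as.numeric(outcome)
  strata <- as.character(strata)
  if (!all(outcome %in% c(0, 1))) stop("outcome must be coded 0/1")
  keep <- stats::complete.cases(x) & !is.na(outcome)
  x <- x[keep, , drop = FALSE]; outcome <- outcome[keep]; strata <- strata[keep]

  cases_per <- tapply(outcome, strata, sum)
  size_per <- tapply(outcome, strata, length)
  ok <- names(cases_per)[cases_per == 1 & size_per >= 2]
  n_dropped <- length(cases_per) - length(ok)
  use <- strata %in% ok
  x <- x[use, , drop = FALSE]; outcome <- outcome[use]; strata <- strata[use]
  if (length(ok) == 0L) stop("no usable strata (need one case and >=1 control each)")

  # informative = some column varies within the stratum
  sp <- split(seq_along(strata), strata)
  informative <- vapply(sp, function(idx) {
    any(apply(x[idx, , drop = FALSE], 2, function(col) any(col != col[1])))
  }, logical(1))
  if (!any(informative)) stop("all strata uninformative: no within-stratum variation")
  sp <- sp[informative]

  p <- ncol(x)
  beta <- numeric(p)
  cll <- function(b) {
    eta <- drop(x %*% b)
    sum(vapply(sp, function(idx) {
      e <- eta[idx]
      m <- max(e)
      e[outcome[idx] == 1] - (m + log(sum(exp(e - m))))
    }, numeric(1)))
  }
  converged <- FALSE
  ll_old <- cll(beta)
  iters <- 0L
  for (it in seq_len(max_iter)) {
    iters <- it
    eta <- drop(x %*% beta)
    grad <- numeric(p)
    hess <- matrix(0, p, p)
    for (idx in sp) {
      e <- eta[idx]
      w <- exp(e - max(e)); w <- w / sum(w)
      xs <- x[idx, , drop = FALSE]
      xbar <- drop(crossprod(w, xs))
      grad <- grad + xs[outcome[idx] == 1, ] - xbar
      hess <- hess + crossprod(xs * w, xs) - tcrossprod(xbar)
    }
    if (max(abs(grad)) < score_tol) { converged <- TRUE; break }
    step <- tryCatch(solve(hess, grad), error = function(e) NULL)
    if (is.null(step)) break
    ll_new <- cll(beta + step)
    half <- 0L
    while ((!is.finite(ll_new) || ll_new < ll_old) && half < 12L) {
      step <- step / 2
      ll_new <- cll(beta + step)
      half <- half + 1L
    }
    beta <- beta + step
    ll_old <- ll_new
  }

  eta <- drop(x %*% beta)
  hess <- matrix(0, p, p)
  for (idx in sp) {
    e <- eta[idx]
    w <- exp(e - max(e)); w <- w / sum(w)
    xs <- x[idx, , drop = FALSE]
    xbar <- drop(crossprod(w, xs))
    hess <- hess + crossprod(xs * w, xs) - tcrossprod(xbar)
  }
  vcv <- tryCatch(solve(hess), error = function(e) NULL)
  if (is.null(vcv) || any(!is.finite(diag(vcv))) || any(diag(vcv) <= 0)) {
    converged <- FALSE
    vcv <- matrix(NA_real_, p, p)
  }
  se <- sqrt(diag(vcv))
  pv <- pmin(2 * stats::pnorm(-abs(beta / se)), 1)
  names(beta) <- names(se) <- colnames(x)
  dimnames(vcv) <- list(colnames(x), colnames(x))

  structure(
    list(coefficients = beta,
         standard_errors = se,
         covariance = vcv,
         log_likelihood = cll(beta),
         p_values = pv,
         converged = converged,
         n_used = length(outcome),
         n_events = sum(outcome),
         iterations = iters,
         n_strata_used = length(sp),
         n_strata_dropped = n_dropped),
    class = "ua_fit")
}

#' @export
coef.ua_fit <- function(object, ...) object$coefficients

#' @export
vcov.ua_fit <- function(object, ...) object$covariance

#' @export
logLik.ua_fit <- function(object, ...) {
  structure(object$log_likelihood, df = length(object$coefficients),
            class = "logLik")
}

#' Wald confidence intervals for a `ua_fit`
#' @param object a `ua_fit`.
#' @param parm coefficients to include (names or indices; default all).
#' @param level confidence level.
#' @param ... unused.
#' @export
confint.ua_fit <- function(object, parm = NULL, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  b <- object$coefficients
  se <- object$standard_errors
  out <- cbind(lower = b - z * se, upper = b + z * se)
  if (!is.null(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' @export
print.ua_fit <- function(x, ...) {
  kind <- if (is.null(x$n_strata_used)) "logistic" else "conditional logistic"
  cat(sprintf("%s fit: %d obs, %d events, %s\n", kind, x$n_used, x$n_events,
              if (x$converged) sprintf("converged in %d iterations", x$iterations)
              else "DID NOT CONVERGE"))
  print(round(cbind(coef = x$coefficients, se = x$standard_errors,
                    p = x$p_values), 5))
  invisible(x)
}

#' @export
summary.ua_fit <- function(object, level = 0.95, ...) {
  ci <- confint(object, level = level)
  data.frame(term = names(object$coefficients),
             estimate = unname(object$coefficients),
             std_error = unname(object$standard_errors),
             odds_ratio = exp(unname(object$coefficients)),
             ci_low = exp(ci[, 1]),
             ci_high = exp(ci[, 2]),
             p_value = unname(object$p_values),
             row.names = NULL)
}
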