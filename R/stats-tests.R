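#' Exact two-sided binomial test for temporal direction
#'
#' Tests whether one ordering of a disease pair dominates, given the counts of
#' persons diagnosed in each order, against a fair-coin null (probability 0.5
#' per person). The two-sided p-value is the sum of probabilities of all
#' outcomes no more likely than the observed one (the minlike convention),
#' capped at 1.
#'
#' @param n_forward count of persons with the pair in the forward order.
#' @param n_reverse count of persons with the pair in the reverse order.
#' @return the exact two-sided p-value (numeric scalar).
#' @examples
#' binomial_direction_test(10, 0)  # 2 * 0.5^10
#' @export
binomial_direction_test <- function(n_forward, n_reverse) {
  n_forward <- as.integer(n_forward)
  n_reverse <- as.integer(n_reverse)
  if (is.na(n_forward) || is.na(n_reverse) || n_forward < 0 || n_reverse < 0) {
    stop("counts must be non-negative integers")
  }
  n <- n_forward + n_reverse
  if (n < 1L) stop("at least one ordered occurrence is required")
  d_obs <- stats::dbinom(n_forward, n, 0.5)
  d_all <- stats::dbinom(0:n, n, 0.5)
  # relative tolerance guards against ties broken by floating-point noise
  min(1, sum(d_all[d_all <= d_obs * (1 + 1e-7)]))
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up FDR adjustment: with m p-values sorted ascending, the adjusted
#' value at rank i is \eqn{\min_{j \ge i} m \, p_{(j)} / j}, capped at 1 and
#' mapped back to input order. Discoveries are declared at `adjusted_p < q`.
#'
#' @param p vector of raw p-values in (0, 1]. NAs are carried through and do
#'   not count towards m.
#' @param q FDR level for the significance flags.
#' @return an object of class `ua_fdr`: list with `raw_p`, `adjusted_p`,
#'   `significant`, `q`, `m`.
#' @export
bh_fdr <- function(p, q = 0.05) {
  p <- as.numeric(p)
  adj <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  if (any(p[ok] <= 0 | p[ok] > 1)) stop("p-values must lie in (0, 1]")
  m <- sum(ok)
  if (m > 0L) {
    ord <- order(p[ok])
    ps <- p[ok][ord]
    stepped <- rev(cummin(rev(m * ps / seq_len(m))))
    adj_ok <- numeric(m)
    adj_ok[ord] <- pmin(stepped, 1)
    adj[ok] <- adj_ok
  }
  structure(list(raw_p = p, adjusted_p = adj,
                 significant = !is.na(adj) & adj < q,
                 q = q, m = m),
            class = "ua_fdr")
}

#' @export
print.ua_fdr <- function(x, ...) {
  cat(sprintf("BH-FDR over %d tests at q = %g: %d significant\n",
              x$m, x$q, sum(x$significant)))
  invisible(x)
}

#' Two-sample heterogeneity z-test on effect estimates
#'
#' Compares two independent effect estimates (typically log odds ratios from
#' two strata, e.g. men vs women) via
#' \eqn{z = (\beta_1 - \beta_2)/\sqrt{se_1^2 + se_2^2}} with a two-sided
#' normal p-value. Vectorized over all arguments.
#'
#' @param beta1,beta2 effect estimates (log-OR scale in the scans).
#' @param se1,se2 their standard errors (must be positive).
#' @return data.frame with columns `z` and `p`.
#' @export
heterogeneity_z <- function(beta1, se1, beta2, se2) {
  if (any(c(se1, se2) <= 0, na.rm = TRUE)) stop("standard errors must be > 0")
  z <- (beta1 - beta2) / sqrt(se1^2 + se2^2)
  data.frame(z = z, p = pmin(2 * stats::pnorm(-abs(z)), 1))
}

#' Restricted cubic spline basis
#'
#' Builds the truncated-power restricted cubic spline basis of Stone and Koo:
#' a linear column plus k-2 cubic columns constrained to be linear beyond the
#' boundary knots. With the package default of five knots (placed by callers
#' at the 5th, 25th, 50th, 75th and 95th percentiles of the exposure) this
#' yields a linear term plus three non-linear terms. Cubic columns are scaled
#' by \eqn{(t_k - t_1)^2} for numerical conditioning; this rescaling does not
#' change the span of the basis and therefore leaves likelihood-ratio tests
#' untouched.
#'
#' @param x numeric vector to expand.
#' @param knots strictly increasing knot locations (length >= 3).
#' @return matrix with `length(knots) - 1` columns: `x`, then `rcs1`...
#' @export
rcs_basis <- function(x, knots) {
  knots <- sort(as.numeric(knots))
  if (anyDuplicated(knots)) stop("knots must be distinct")
  k <- length(knots)
  if (k < 3L) stop("need at least 3 knots")
  tk <- knots[k]; tk1 <- knots[k - 1L]
  scale2 <- (tk - knots[1])^2
  pos3 <- function(u) pmax(u, 0)^3
  out <- matrix(0, length(x), k - 1L)
  out[, 1L] <- x
  for (j in seq_len(k - 2L)) {
    tj <- knots[j]
    out[, j + 1L] <- (pos3(x - tj) -
                        pos3(x - tk1) * (tk - tj) / (tk - tk1) +
                        pos3(x - tk) * (tk1 - tj) / (tk - tk1)) / scale2
  }
  colnames(out) <- c("x", paste0("rcs", seq_len(k - 2L)))
  out
}

#' Likelihood-ratio test for non-linearity
#'
#' Compares a fit with the exposure entered linearly against a fit with the
#' restricted-cubic-spline expansion of the same exposure (same rows, same
#' covariates). The statistic is twice the log-likelihood gain, referred to a
#' chi-square with degrees of freedom equal to the number of extra spline
#' columns (3 under the five-knot default).
#'
#' @param fit_linear,fit_spline nested `ua_fit` objects from [fit_logistic()]
#'   on identical observations.
#' @return list with `lr`, `df`, `p`.
#' @export
nonlinearity_test <- function(fit_linear, fit_spline) {
  if (fit_linear$n_used != fit_spline$n_used) {
    stop("fits are not on the same observations")
  }
  df <- length(fit_spline$coefficients) - length(fit_linear$coefficients)
  if (df < 0L) stop("spline fit has fewer parameters than the linear fit")
  lr <- 2 * (fit_spline$log_likelihood - fit_linear$log_likelihood)
  if (lr < -1e-6) {
    stop("negative likelihood-ratio statistic: a fit failed to converge")
  }
  lr <- max(lr, 0)
  if (df == 0L) return(list(lr = lr, df = 0L, p = 1))
  list(lr = lr, df = df, p = stats::pchisq(lr, df, lower.tail = FALSE))
}
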