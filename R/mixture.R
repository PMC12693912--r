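#' Fit a Gaussian mixture with known per-observation variances
#'
#' Meta-analysis model for projected QTL positions: observation `x_i` (a
#' QTL peak on the consensus map) is drawn from one of `k` loci with
#' probability `pi_k`, with a KNOWN positional standard deviation `s_i`
#' derived from its projected confidence interval. The likelihood is
#' \deqn{\ln L = \sum_i \ln \sum_k \pi_k \phi(x_i; \mu_k, s_i^2)}
#' and only the component means and proportions are free (2k - 1
#' parameters). Fitting is by EM from `n_starts` quantile-spread
#' initializations, returning the best-likelihood run.
#'
#' @param positions Numeric vector of projected peak positions (cM).
#' @param sds Positive numeric vector of per-QTL positional standard
#'   deviations (cM), same length.
#' @param k Number of mixture components, `1 <= k <= length(positions)`.
#' @param n_starts Number of EM initializations.
#' @param tol Convergence tolerance on the log-likelihood increment.
#' @param max_iter Maximum EM iterations per start.
#' @param seed Optional integer seed for the initialization jitter.
#' @return Object of class `mixture_fit`: list with `k`, `means` (sorted
#'   ascending), `weights`, `loglik`, `responsibilities` (n x k),
#'   `converged`, `n_iter` and `loglik_trace` of the winning run.
#' @export
fit_mixture <- function(positions, sds, k, n_starts = 20, tol = 1e-8,
                        max_iter = 2000, seed = NULL) {
  x <- as.numeric(positions); s <- as.numeric(sds)
  n <- length(x)
  if (length(s) != n) mq_value_error("positions and sds differ in length")
  if (any(!is.finite(x)) || any(!is.finite(s)))
    mq_value_error("non-finite position or sd")
  if (any(s <= 0)) mq_value_error("all sds must be > 0")
  if (k < 1 || k > n) mq_value_error("k must satisfy 1 <= k <= n")
  if (!is.null(seed)) set.seed(seed)

  w <- 1 / s^2
  log_norm <- -log(s) - 0.5 * log(2 * pi)  # per-observation constant
  jitter_sd <- max(diff(range(x)), 1e-6) / (4 * k)
  best <- NULL
  if (k == 1L) n_starts <- 1L  # closed-form fixed point; one start suffices
  for (st in seq_len(n_starts)) {
    mu <- as.numeric(quantile(x, probs = seq_len(k) / (k + 1), names = FALSE))
    if (st > 1) mu <- mu + rnorm(k, 0, jitter_sd)
    pi_k <- rep(1 / k, k)
    ll_prev <- -Inf
    trace <- numeric(0)
    converged <- FALSE
    r <- matrix(1, n, k)
    for (it in seq_len(max_iter)) {
      # E-step in log space; -log(s) recycles down columns
      logphi <- -0.5 * outer(x, mu, "-")^2 * w + log_norm
      logw <- sweep(logphi, 2, log(pmax(pi_k, 1e-300)), "+")
      lse <- row_logsumexp(logw)
      ll <- sum(lse)
      r <- exp(logw - lse)
      r[r < 1e-300] <- 1e-300
      r <- r / rowSums(r)
      trace <- c(trace, ll)
      if (is.finite(ll_prev) && abs(ll - ll_prev) < tol) {
        converged <- TRUE
        break
      }
      ll_prev <- ll
      # M-step: inverse-variance-weighted means, mean responsibilities
      denom <- colSums(r * w)
      mu_new <- colSums(r * w * x) / denom
      mu <- ifelse(is.finite(mu_new), mu_new, mu)
      pi_k <- colMeans(r)
    }
    fit <- list(k = k, means = mu, weights = pi_k, loglik = ll,
                responsibilities = r, converged = converged, n_iter = it,
                loglik_trace = trace)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  o <- order(best$means)
  best$means <- best$means[o]
  best$weights <- best$weights[o]
  best$responsibilities <- best$responsibilities[, o, drop = FALSE]
  class(best) <- "mixture_fit"
  best
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("Gaussian mixture fit: K = %d, logLik = %.4f (%s, %d iter)\n",
              x$k, x$loglik,
              if (x$converged) "converged" else "not converged", x$n_iter))
  cat("  means (cM):", paste(sprintf("%.3f", x$means), collapse = ", "), "\n")
  cat("  weights:   ", paste(sprintf("%.3f", x$weights), collapse = ", "), "\n")
  invisible(x)
}

#' Information criteria for a mixture fit
#'
#' With deviance `D = -2 lnL`, free-parameter count `p = 2k - 1` and `n`
#' observations:
#' `AIC = D + 2p`; `AICc = AIC + 2p(p+1)/(n-p-1)`; `AIC3 = D + 3p`;
#' `BIC = D + p ln(n)`; `AWE = -2 lnL_c + 2p(3/2 + ln n)`, where the
#' completed-data log-likelihood is `lnL_c = lnL + sum_ik r_ik ln r_ik`
#' (with `0 ln 0 = 0`).
#'
#' @param fit A `mixture_fit`.
#' @param n_obs Number of observations (defaults to the responsibility
#'   matrix's row count).
#' @return One-row `data.frame`: `k p_free n_obs aic aicc aic3 bic awe`.
#' @export
information_criteria <- function(fit, n_obs = nrow(fit$responsibilities)) {
  k <- fit$k
  p <- 2L * k - 1L
  d <- -2 * fit$loglik
  aic <- d + 2 * p
  if (n_obs > p + 1) {
    aicc <- aic + 2 * p * (p + 1) / (n_obs - p - 1)
  } else {
    warning("AICc undefined for n <= p + 1; reported as +Inf")
    aicc <- Inf
  }
  r <- fit$responsibilities
  ent <- sum(ifelse(r > 0, r * log(r), 0))
  llc <- fit$loglik + ent
  awe <- -2 * llc + 2 * p * (1.5 + log(n_obs))
  data.frame(k = k, p_free = p, n_obs = n_obs, aic = aic, aicc = aicc,
             aic3 = d + 3 * p, bic = d + p * log(n_obs), awe = awe)
}

#' Select the mixture component count by majority vote
#'
#' Each of the five criteria (AIC, AICc, AIC3, BIC, AWE) votes for the `k`
#' at which it is minimal (smallest `k` on exact ties). The `k` holding at
#' least three of the five minima is selected; if no `k` reaches three, the
#' `k` with the most minima wins; remaining ties go to the smallest `k`
#' (parsimony).
#'
#' @param rows `data.frame` of criterion rows (one per candidate `k`), as
#'   stacked [information_criteria()] output.
#' @return Selected `k` (integer) with attribute `"minima"`, the named
#'   vector of per-criterion argmin `k`s.
#' @export
select_model <- function(rows) {
  if (is.null(rows) || nrow(rows) == 0) mq_value_error("empty criteria table")
  crits <- c("aic", "aicc", "aic3", "bic", "awe")
  rows <- rows[order(rows$k), , drop = FALSE]
  minima <- vapply(crits, function(cc) rows$k[which.min(rows[[cc]])],
                   numeric(1))
  counts <- table(minima)
  top <- as.numeric(names(counts)[counts == max(counts)])
  k <- as.integer(min(top))
  attr(k, "minima") <- minima
  k
}
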