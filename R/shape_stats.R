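#' Sarle's bimodality coefficient
#'
#' `BC = (g1^2 + 1) / (g2 + 3 (n-1)^2 / ((n-2)(n-3)))` where `g1` is the
#' adjusted Fisher-Pearson sample skewness and `g2` the bias-corrected excess
#' kurtosis (both e1071 type 2). A continuous uniform distribution gives
#' `BC = 5/9 ~ 0.5556`, which is the conventional unimodal/bimodal decision
#' threshold (0.555): heavier-than-uniform shoulders, as produced by two
#' separated modes, push BC above it.
#'
#' @param values Numeric vector, `n >= 4`, nonzero variance.
#' @param threshold Decision threshold (default 0.555).
#' @return A `bimodality_result`: `n`, `skewness`, `excess_kurtosis`, `bc`,
#'   `threshold`, `is_bimodal`.
#' @export
bimodality_coefficient <- function(values, threshold = 0.555) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 4) stop("bimodality coefficient needs n >= 4", call. = FALSE)
  if (stats::sd(values) == 0) stop("zero variance: statistic undefined", call. = FALSE)
  g1 <- e1071::skewness(values, type = 2)
  g2 <- e1071::kurtosis(values, type = 2)
  bc <- (g1^2 + 1) / (g2 + 3 * (n - 1)^2 / ((n - 2) * (n - 3)))
  structure(list(n = n, skewness = g1, excess_kurtosis = g2, bc = bc,
                 threshold = threshold, is_bimodal = bc > threshold),
            class = "bimodality_result")
}

#' @export
print.bimodality_result <- function(x, ...) {
  cat(sprintf("<bimodality_result> BC = %.4f (threshold %.3f) -> %s (n = %d, skew %.3f, ex.kurt %.3f)\n",
              x$bc, x$threshold, if (x$is_bimodal) "bimodal" else "unimodal",
              x$n, x$skewness, x$excess_kurtosis))
  invisible(x)
}

#' Fit a 1-D Gaussian mixture by EM
#'
#' `k = 1` is the closed form (sample mean, biased variance). `k = 2` runs EM
#' from a below/above-median split plus `n_restarts` random-responsibility
#' starts, keeping the best log-likelihood; component variances are floored at
#' `(tolerance * sd(values))^2` to prevent collapse onto a single point.
#' Deterministic given `seed`.
#'
#' @param values Numeric vector with `n >= 10 * k` finite values.
#' @param k Number of components, 1 or 2.
#' @param n_restarts Random restarts for `k = 2`.
#' @param tolerance Convergence tolerance on the log-likelihood (also sets the
#'   variance floor, see above).
#' @param max_iter EM iteration cap per start.
#' @param seed Seed for the random restarts.
#' @return A `gaussian_mixture_fit`: `k`, `weights`, `means`, `sds`, `loglik`,
#'   `converged`, `n`.
#' @export
fit_gaussian_mixture_1d <- function(values, k = 2, n_restarts = 10,
                                    tolerance = 1e-6, max_iter = 500, seed = 1) {
  values <- as.numeric(values)
  n <- length(values)
  if (!k %in% c(1, 2)) stop("k must be 1 or 2", call. = FALSE)
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)
  if (n < 10 * k) stop(sprintf("need n >= %d for k = %d", 10 * k, k), call. = FALSE)
  if (k == 1) {
    mu <- mean(values); v <- mean((values - mu)^2)
    ll <- sum(stats::dnorm(values, mu, sqrt(v), log = TRUE))
    return(structure(list(k = 1L, weights = 1, means = mu, sds = sqrt(v),
                          loglik = ll, converged = TRUE, n = n),
                     class = "gaussian_mixture_fit"))
  }
  var_floor <- (tolerance * stats::sd(values))^2
  run_em <- function(resp) {
    ll_prev <- -Inf
    for (it in seq_len(max_iter)) {
      w <- colMeans(resp)
      mu <- colSums(resp * values) / colSums(resp)
      v <- pmax(colSums(resp * outer(values, mu, `-`)^2) / colSums(resp), var_floor)
      logd <- vapply(1:2, function(j)
        log(w[j]) + stats::dnorm(values, mu[j], sqrt(v[j]), log = TRUE),
        numeric(n))
      m <- pmax(logd[, 1], logd[, 2])
      lse <- m + log(exp(logd[, 1] - m) + exp(logd[, 2] - m))
      ll <- sum(lse)
      resp <- exp(logd - lse)
      if (is.finite(ll) && abs(ll - ll_prev) < tolerance)
        return(list(ll = ll, w = w, mu = mu, v = v, converged = TRUE))
      ll_prev <- ll
    }
    list(ll = ll_prev, w = w, mu = mu, v = v, converged = FALSE)
  }
  starts <- list({  # deterministic start: split at the median
    lo <- values <= stats::median(values)
    cbind(as.numeric(lo), as.numeric(!lo))
  })
  fits <- .with_seed(seed, {
    rand <- lapply(seq_len(n_restarts), function(i) {
      r1 <- stats::runif(n)
      cbind(r1, 1 - r1)
    })
    lapply(c(starts, rand), run_em)
  })
  best <- fits[[which.max(vapply(fits, `[[`, numeric(1), "ll"))]]
  if (!any(vapply(fits, `[[`, logical(1), "converged")))
    warning("EM did not converge in any start; returning best iterate", call. = FALSE)
  ord <- order(best$mu)
  structure(list(k = 2L, weights = unname(best$w[ord]), means = unname(best$mu[ord]),
                 sds = unname(sqrt(best$v[ord])), loglik = best$ll,
                 converged = best$converged, n = n),
            class = "gaussian_mixture_fit")
}

#' @export
print.gaussian_mixture_fit <- function(x, ...) {
  cat(sprintf("<gaussian_mixture_fit> k = %d, loglik %.2f\n", x$k, x$loglik))
  for (j in seq_len(x$k))
    cat(sprintf("  comp %d: weight %.3f, mean %.4g, sd %.4g\n",
                j, x$weights[j], x$means[j], x$sds[j]))
  invisible(x)
}

#' Select 1 vs 2 Gaussian mixture components by BIC
#'
#' `BIC_k = -2 loglik + p_k log(n)` with `p_1 = 2` and `p_2 = 5` free
#' parameters (k means, k standard deviations, k - 1 weights).
#' `delta_bic = BIC_2 - BIC_1`; a negative value favours the two-component
#' model.
#'
#' @param values Numeric vector, `n >= 20`.
#' @param seed Seed forwarded to the k = 2 EM fit.
#' @param ... Further arguments to [fit_gaussian_mixture_1d()].
#' @return A `mixture_select_result`: `loglik_1`, `loglik_2`, `bic_1`,
#'   `bic_2`, `delta_bic`, `selected_components`, and the two-component fit
#'   as `fit_2`.
#' @export
select_mixture_model <- function(values, seed = 1, ...) {
  n <- length(values)
  if (n < 20) stop("mixture selection needs n >= 20", call. = FALSE)
  f1 <- fit_gaussian_mixture_1d(values, k = 1)
  f2 <- fit_gaussian_mixture_1d(values, k = 2, seed = seed, ...)
  bic1 <- -2 * f1$loglik + 2 * log(n)
  bic2 <- -2 * f2$loglik + 5 * log(n)
  structure(list(loglik_1 = f1$loglik, loglik_2 = f2$loglik,
                 bic_1 = bic1, bic_2 = bic2, delta_bic = bic2 - bic1,
                 selected_components = if (bic2 - bic1 < 0) 2L else 1L,
                 fit_2 = f2, n = n),
            class = "mixture_select_result")
}

#' @export
print.mixture_select_result <- function(x, ...) {
  cat(sprintf("<mixture_select_result> BIC1 %.1f, BIC2 %.1f, dBIC %.1f -> %d component(s)\n",
              x$bic_1, x$bic_2, x$delta_bic, x$selected_components))
  invisible(x)
}
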