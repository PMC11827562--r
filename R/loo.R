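#' Fit a generalized Pareto distribution to sample tails
#'
#' Profile-likelihood method of Zhang and Stephens (2009) with the usual
#' weakly-informative prior adjustment on the shape, as used for
#' Pareto-smoothed importance sampling.
#'
#' @param x positive exceedances (threshold already subtracted).
#' @return list with shape \code{k} and scale \code{sigma}.
#' @export
gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n < 5) return(list(k = Inf, sigma = NA_real_))
  prior_bs <- 3
  m <- 30 + floor(sqrt(n))
  xstar <- x[max(1, floor(n / 4 + 0.5))]
  theta <- 1 / x[n] + (1 - sqrt(m / (seq_len(m) - 0.5))) / (prior_bs * xstar)
  k_j <- vapply(theta, function(th) -mean(log1p(-th * x)), 0)
  l_j <- n * (log(theta / k_j) + k_j - 1)
  w <- exp(l_j - max(l_j))
  w <- w / sum(w)
  theta_hat <- sum(theta * w)
  # Zhang-Stephens shape (positive = bounded tail); convert to the xi
  # convention where positive = heavy tail
  k_zs <- -mean(log1p(-theta_hat * x))
  sigma <- k_zs / theta_hat
  xi <- -k_zs
  # shape regularized toward 0.5 with 10 pseudo-observations
  xi <- xi * n / (n + 10) + 0.5 * 10 / (n + 10)
  list(k = xi, sigma = sigma)
}

gpd_quantile <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma * expm1(-k * log1p(-p)) / k
}

# Pareto-smooth one vector of log importance ratios; returns smoothed log
# weights (unnormalized) and the tail shape diagnostic khat
psis_smooth <- function(lr) {
  S <- length(lr)
  tail_len <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  lr <- lr - max(lr)
  if (tail_len < 5) return(list(lw = lr, khat = Inf))
  ord <- order(lr)
  tail_idx <- ord[(S - tail_len + 1):S]
  cut_idx <- ord[S - tail_len]
  lcut <- lr[cut_idx]
  exceed <- exp(lr[tail_idx]) - exp(lcut)
  if (all(exceed <= 0)) return(list(lw = lr, khat = -Inf))
  fit <- gpd_fit(exceed)
  if (!is.finite(fit$k)) return(list(lw = lr, khat = Inf))
  qq <- gpd_quantile((seq_len(tail_len) - 0.5) / tail_len, fit$k, fit$sigma)
  smoothed <- log(qq + exp(lcut))
  # order-preserving replacement of the tail, truncated at the raw maximum
  smoothed <- pmin(smoothed, 0)
  lr[tail_idx[order(lr[tail_idx])]] <- smoothed
  list(lw = lr, khat = fit$k)
}

#' PSIS-LOO: approximate leave-one-out cross-validation
#'
#' Estimates the expected log pointwise predictive density (ELPD) by
#' Pareto-smoothed importance sampling over posterior draws, one importance
#' distribution per held-out trial.
#'
#' @param loglik draws x trials pointwise log-likelihood matrix (see
#'   \code{\link{pointwise_loglik}}).
#' @param model name carried into comparison tables.
#' @return object of class \code{voi_loo}: total \code{elpd}, its standard
#'   error, \code{pointwise} contributions, and the Pareto-\code{khat}
#'   diagnostic per trial (values above 0.7 indicate unreliable smoothing and
#'   are flagged by \code{\link{compare_models}}).
#' @export
psis_loo <- function(loglik, model = "model") {
  loglik <- as.matrix(loglik)
  n <- ncol(loglik)
  pointwise <- numeric(n)
  khat <- numeric(n)
  for (i in seq_len(n)) {
    ll <- loglik[, i]
    sm <- psis_smooth(-ll)
    lw <- sm$lw - logsumexp(sm$lw)
    pointwise[i] <- logsumexp(lw + ll)
    khat[i] <- sm$khat
  }
  structure(list(model = model, elpd = sum(pointwise),
                 se = sqrt(n * stats::var(pointwise)),
                 pointwise = pointwise, khat = khat, n = n),
            class = "voi_loo")
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' @export
print.voi_loo <- function(x, ...) {
  cat(sprintf("PSIS-LOO (%s): elpd = %.1f (SE %.1f), n = %d, khat > 0.7: %d\n",
              x$model, x$elpd, x$se, x$n, sum(x$khat > 0.7)))
  invisible(x)
}

#' Compare models by PSIS-LOO
#'
#' Ranks models by ELPD and reports pairwise differences to the top model
#' with standard errors computed from the pointwise contributions.
#'
#' @param loo_results list of \code{\link{psis_loo}} results on the same
#'   trials.
#' @return data frame of class \code{voi_loo_compare}, best model first:
#'   \code{model}, \code{elpd}, \code{se}, \code{elpd_diff}, \code{se_diff},
#'   \code{n_high_khat}.
#' @export
compare_models <- function(loo_results) {
  if (inherits(loo_results, "voi_loo")) loo_results <- list(loo_results)
  stopifnot(all(vapply(loo_results, inherits, TRUE, "voi_loo")))
  ns <- vapply(loo_results, function(l) l$n, 0L)
  if (length(unique(ns)) != 1)
    stop("models were evaluated on different trial sets")
  ord <- order(vapply(loo_results, function(l) l$elpd, 0), decreasing = TRUE)
  loo_results <- loo_results[ord]
  best <- loo_results[[1]]
  out <- data.frame(
    model = vapply(loo_results, function(l) l$model, ""),
    elpd = vapply(loo_results, function(l) l$elpd, 0),
    se = vapply(loo_results, function(l) l$se, 0),
    elpd_diff = vapply(loo_results, function(l) l$elpd - best$elpd, 0),
    se_diff = vapply(loo_results, function(l) {
      d <- l$pointwise - best$pointwise
      if (all(d == 0)) 0 else sqrt(length(d) * stats::var(d))
    }, 0),
    n_high_khat = vapply(loo_results, function(l) sum(l$khat > 0.7), 0L))
  if (any(out$n_high_khat > 0))
    warning("high Pareto-khat (> 0.7) for ",
            paste(out$model[out$n_high_khat > 0], collapse = ", "),
            ": PSIS-LOO estimates may be unreliable")
  class(out) <- c("voi_loo_compare", "data.frame")
  out
}
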