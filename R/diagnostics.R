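#' Split-Rhat convergence diagnostic
#'
#' Potential scale reduction factor computed after splitting each chain in
#' half, so within-chain trends register as apparent non-convergence.
#'
#' @param x numeric vector of draws, stacked chain by chain.
#' @param chain_id integer chain label per draw.
#' @return scalar split-Rhat (NA for constant draws).
#' @export
split_rhat <- function(x, chain_id) {
  halves <- split_chain_halves(x, chain_id)
  n <- min(lengths(halves))
  halves <- lapply(halves, function(h) h[seq_len(n)])
  if (n < 2) return(NA_real_)
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, stats::var, 0)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (!is.finite(W) || W == 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

split_chain_halves <- function(x, chain_id) {
  out <- list()
  for (ch in unique(chain_id)) {
    v <- x[chain_id == ch]
    h <- floor(length(v) / 2)
    out <- c(out, list(v[seq_len(h)], v[(h + 1):(2 * h)]))
  }
  out
}

#' Effective sample size
#'
#' Classic autocorrelation-based ESS over split chains with Geyer's initial
#' positive sequence truncation.
#'
#' @inheritParams split_rhat
#' @return scalar effective sample size.
#' @export
ess_basic <- function(x, chain_id) {
  halves <- split_chain_halves(x, chain_id)
  n <- min(lengths(halves))
  halves <- lapply(halves, function(h) h[seq_len(n)])
  m <- length(halves)
  if (n < 4) return(NA_real_)
  vars <- vapply(halves, stats::var, 0)
  means <- vapply(halves, mean, 0)
  W <- mean(vars)
  var_plus <- W * (n - 1) / n + stats::var(means)
  if (!is.finite(var_plus) || var_plus == 0) return(NA_real_)
  acov <- sapply(halves, function(h) {
    a <- stats::acf(h, lag.max = n - 1, plot = FALSE, type = "covariance")
    as.numeric(a$acf)
  })
  rho <- 1 - (W - rowMeans(acov)) / var_plus
  # Geyer initial positive sequence on paired sums
  tau <- 1
  t <- 1
  while (t + 1 < length(rho)) {
    pair <- rho[t + 1] + ifelse(t + 2 <= length(rho), rho[t + 2], 0)
    if (pair < 0) break
    tau <- tau + 2 * pair
    t <- t + 2
  }
  max(m * n / tau, 1)
}
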