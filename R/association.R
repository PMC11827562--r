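#' Gauss-Hermite quadrature nodes and weights
#'
#' Golub-Welsch computation from the Jacobi matrix of the (physicists')
#' Hermite polynomials; used to marginalize the random intercept of the mixed
#' ordinal model.
#'
#' @param n number of nodes.
#' @return list with \code{nodes} and \code{weights} (weights sum to
#'   \code{sqrt(pi)}).
#' @export
gauss_hermite <- function(n) {
  if (n == 1) return(list(nodes = 0, weights = sqrt(pi)))
  off <- sqrt(seq_len(n - 1) / 2)
  J <- matrix(0, n, n)
  J[cbind(seq_len(n - 1), 2:n)] <- off
  J[cbind(2:n, seq_len(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord],
       weights = sqrt(pi) * e$vectors[1, ord]^2)
}

zscore_strict <- function(x, label) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0)
    stop("degenerate-variance: ", label, " has zero variance")
  (x - mean(x)) / s
}

# design matrix for the behavioural regression: z-scored outcome, probability,
# cost (rank or dollars), their interactions, and the four factor scores
ordinal_design <- function(trials, scores, cost_scale, interactions) {
  outcome <- ifelse(trials$valence == "gain", 1, -1)
  cost <- if (cost_scale == "rank") trials$cost_rank else trials$cost_dollars
  X <- cbind(outcome = zscore_strict(outcome, "outcome"),
             probability = zscore_strict(trials$p, "probability"),
             cost = zscore_strict(cost, "cost"))
  if (interactions %in% c("pairwise", "all")) {
    X <- cbind(X,
               "outcome:probability" = X[, "outcome"] * X[, "probability"],
               "outcome:cost" = X[, "outcome"] * X[, "cost"],
               "probability:cost" = X[, "probability"] * X[, "cost"])
  }
  if (interactions == "all") {
    X <- cbind(X, "outcome:probability:cost" =
                 X[, "outcome"] * X[, "probability"] * X[, "cost"])
  }
  sidx <- match(trials$subject, scores$subject)
  if (anyNA(sidx)) stop("factor scores missing for some subjects in trials")
  for (f in factor_names())
    X <- cbind(X, zscore_strict(scores[[f]][sidx], f))
  colnames(X)[(ncol(X) - 3):ncol(X)] <- factor_names()
  X
}

#' Mixed-effects ordered logistic regression
#'
#' Cumulative-logit model for the 5 Likert categories with z-scored fixed
#' effects of outcome valence, probability, information cost, their
#' interactions, and the four anxiety factor scores, plus a random intercept
#' per subject. Fitted by maximum likelihood with Gauss-Hermite quadrature
#' over the random intercept; standard errors come from the observed
#' information at the optimum.
#'
#' @param trials trial table.
#' @param scores factor scores with a \code{subject} column.
#' @param cost_scale z-score the rank-transformed cost ("rank", default,
#'   consistent with the process model) or the raw dollar cost ("dollars").
#' @param interactions "all" (pairwise + 3-way, default), "pairwise", or
#'   "none".
#' @param n_quad quadrature nodes (default 30).
#' @return object of class \code{voi_ordinal_fit}: coefficient table
#'   (estimate, SE, z, p), random-intercept SD, log-likelihood, counts.
#' @export
ordinal_mixed_regression <- function(trials, scores,
                                     cost_scale = c("rank", "dollars"),
                                     interactions = c("all", "pairwise",
                                                      "none"),
                                     n_quad = 30) {
  cost_scale <- match.arg(cost_scale)
  interactions <- match.arg(interactions)
  if (any(!trials$response %in% 1:5)) stop("responses must be in 1..5")
  tab <- table(trials$response)
  if (length(tab) < 2)
    stop("degenerate response distribution: all responses in category ",
         names(tab))
  X <- ordinal_design(trials, scores, cost_scale, interactions)
  subjects <- sort(unique(trials$subject))
  subj <- as.integer(match(trials$subject, subjects) - 1L)
  gh <- gauss_hermite(n_quad)
  K <- 5L
  p <- ncol(X)

  obj <- function(th) ordmix_nll_grad(th, as.integer(trials$response), X,
                                      subj, length(subjects), K,
                                      gh$nodes, gh$weights)
  fn <- function(th) obj(th)$nll
  gr <- function(th) obj(th)$grad

  # start from the empirical cumulative logits, zero betas, sigma = 0.5
  cum <- cumsum(tabulate(trials$response, K))[1:(K - 1)] / nrow(trials)
  cum <- pmin(pmax(cum, 1e-3), 1 - 1e-3)
  kap0 <- stats::qlogis(cum)
  th0 <- c(kap0[1], log(pmax(diff(kap0), 1e-2)), rep(0, p), log(0.5))
  opt <- stats::nlminb(th0, fn, gr,
                       control = list(iter.max = 500, eval.max = 1000))
  if (opt$convergence != 0 && opt$message != "false convergence (8)")
    warning("ordinal fit: ", opt$message)
  if (!is.finite(opt$objective))
    stop("ordinal fit failed (non-finite likelihood); possible separation")

  H <- stats::optimHess(opt$par, fn, gr)
  V <- tryCatch(solve(H), error = function(e) {
    warning("singular Hessian; SEs from pseudo-inverse (possible separation)")
    MASS::ginv(H)
  })
  se_all <- sqrt(pmax(diag(V), 0))

  ncut <- K - 1L
  idx <- ncut + seq_len(p)
  est <- opt$par[idx]
  se <- se_all[idx]
  z <- est / se
  coef_tab <- data.frame(term = colnames(X), estimate = est, se = se, z = z,
                         p_value = 2 * stats::pnorm(-abs(z)))
  kappa <- cumsum(c(opt$par[1], exp(opt$par[2:ncut])))
  structure(list(coefficients = coef_tab, kappa = kappa,
                 sigma_subject = exp(opt$par[ncut + p + 1]),
                 sigma_se = se_all[ncut + p + 1] *
                   exp(opt$par[ncut + p + 1]),
                 loglik = -opt$objective,
                 n_subjects = length(subjects), n_trials = nrow(trials),
                 cost_scale = cost_scale, interactions = interactions,
                 convergence = opt$convergence),
            class = "voi_ordinal_fit")
}

#' @export
print.voi_ordinal_fit <- function(x, ...) {
  cat(sprintf("Mixed-effects ordered logistic (%d subjects, %d trials)\n",
              x$n_subjects, x$n_trials))
  cat(sprintf("  random-intercept SD: %.3f; logLik %.1f\n",
              x$sigma_subject, x$loglik))
  print(x$coefficients, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Linear regressions of model variables/parameters on anxiety factors
#'
#' For each response in \{mean trial-level VOI, U_info, U_plan; posterior-mean
#' U_outcome, C_plan, C_info, U_leisure; log(s_gain / s_loss)\}, fits one
#' ordinary linear regression on the four factor scores. Inputs and outputs
#' are z-scored, so coefficients are standardized.
#'
#' @param fit a \code{voi_fit}, or a data frame with a \code{subject} column
#'   and per-subject response columns.
#' @param scores factor scores with a \code{subject} column.
#' @return data frame of class \code{voi_param_regressions}: one row per
#'   response x factor with standardized \code{estimate}, \code{se}, 95\%
#'   \code{ci_lower}/\code{ci_upper} and \code{p_value}; degenerate
#'   zero-variance responses are flagged, not fitted.
#' @export
parameter_regressions <- function(fit, scores) {
  df <- if (inherits(fit, "voi_fit")) subject_variable_table(fit) else fit
  responses <- setdiff(names(df), "subject")
  sidx <- match(df$subject, scores$subject)
  if (anyNA(sidx)) stop("factor scores missing for some subjects")
  Fm <- vapply(factor_names(), function(f) zscore_strict(scores[[f]][sidx], f),
               numeric(nrow(df)))
  out <- lapply(responses, function(rv) {
    y <- df[[rv]]
    if (!is.finite(stats::sd(y)) || stats::sd(y) == 0)
      return(data.frame(response = rv, term = factor_names(),
                        estimate = NA_real_, se = NA_real_,
                        ci_lower = NA_real_, ci_upper = NA_real_,
                        p_value = NA_real_, degenerate = TRUE))
    m <- stats::lm(zscore(y) ~ Fm)
    sm <- summary(m)$coefficients[-1, , drop = FALSE]
    ci <- stats::confint(m)[-1, , drop = FALSE]
    data.frame(response = rv, term = factor_names(),
               estimate = sm[, 1], se = sm[, 2],
               ci_lower = ci[, 1], ci_upper = ci[, 2],
               p_value = sm[, 4], degenerate = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("voi_param_regressions", "data.frame")
  out
}

#' Per-subject model variables and parameters
#'
#' Posterior-mean parameters plus trial-averaged latent variables (VOI,
#' U_info, U_plan) and the log outcome-scaling ratio, one row per subject —
#' the response set of \code{\link{parameter_regressions}}.
#'
#' @param fit a \code{voi_fit}.
#' @return data frame with columns \code{subject}, \code{VOI}, \code{U_info},
#'   \code{U_plan}, \code{U_outcome}, \code{C_plan}, \code{C_info},
#'   \code{U_leisure}, \code{log_scale_ratio}.
#' @export
subject_variable_table <- function(fit) {
  stopifnot(inherits(fit, "voi_fit"))
  lat <- fit$trial_latents
  agg <- stats::aggregate(lat[c("voi", "u_info", "u_plan")],
                          by = list(subject = lat$subject), FUN = mean)
  sm <- fit$subject_means
  agg <- agg[match(sm$subject, agg$subject), ]
  data.frame(subject = sm$subject,
             VOI = agg$voi, U_info = agg$u_info, U_plan = agg$u_plan,
             U_outcome = sm$U_outcome, C_plan = sm$C_plan,
             C_info = sm$C_info, U_leisure = sm$U_leisure,
             log_scale_ratio = log(sm$s_gain / sm$s_loss))
}

#' Cell means of willingness to pay
#'
#' Mean and SEM of the display score (-2..+2) in every outcome x probability
#' x cost cell of the design.
#'
#' @param trials trial table with \code{display_score} (recomputed from
#'   \code{response} if absent).
#' @return data frame with \code{valence}, \code{p}, \code{cost_dollars},
#'   \code{n}, \code{mean_score}, \code{sem}; empty cells are absent.
#' @export
summarize_willingness <- function(trials) {
  if (is.null(trials$display_score))
    trials$display_score <- likert_display_score(trials$response)
  by <- trials[c("valence", "p", "cost_dollars")]
  agg <- stats::aggregate(trials$display_score, by = by, FUN = function(x)
    c(n = length(x), mean = mean(x),
      sem = stats::sd(x) / sqrt(length(x))))
  out <- cbind(agg[names(by)], as.data.frame(agg$x))
  names(out) <- c("valence", "p", "cost_dollars", "n", "mean_score", "sem")
  out[order(out$valence, out$p, out$cost_dollars), , drop = FALSE]
}
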