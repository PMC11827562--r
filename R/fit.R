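#' Hierarchical model specification
#'
#' The full model estimates six parameters per subject (\code{U_outcome},
#' \code{C_plan}, \code{C_info}, \code{U_leisure}, \code{s_gain},
#' \code{s_loss}), four population hyper-means (for the first four), and four
#' shared cut points. Two reduced variants are available: \code{no_scaling}
#' fixes \code{s_gain = s_loss = 1}; \code{shared_Cinfo} replaces the
#' per-subject information costs with a single shared \code{C_info}.
#'
#' Priors: subject parameters follow a normalized truncated normal
#' \code{N(mu, subj_sd)} bounded below at 0 (the \code{-log Phi(mu/sd)}
#' normalization is included, so \code{mu} retains its truncated-normal
#' meaning), hyper-means \code{mu ~ N(0, mu_prior_sd)}, scalings
#' \code{~ N(scale_mean, scale_sd)} bounded below at 0, and each cut point
#' \code{~ N(0, kappa_sd)} subject to ordering.
#'
#' @param variant one of "full", "no_scaling", "shared_Cinfo".
#' @param mu_prior_sd SD of the hyper-mean prior (study value 5).
#' @param subj_sd between-subject SD (study value 1).
#' @param scale_mean,scale_sd prior mean/SD of the outcome scalings (1, 1).
#' @param kappa_sd SD of the weakly-informative cut-point prior.
#' @return list of class \code{voi_model_spec}.
#' @export
model_spec <- function(variant = c("full", "no_scaling", "shared_Cinfo"),
                       mu_prior_sd = 5, subj_sd = 1,
                       scale_mean = 1, scale_sd = 1, kappa_sd = 10) {
  variant <- match.arg(variant)
  structure(list(variant = variant,
                 scaling = variant != "no_scaling",
                 shared_ci = variant == "shared_Cinfo",
                 priors = list(mu_prior_sd = mu_prior_sd, subj_sd = subj_sd,
                               scale_mean = scale_mean, scale_sd = scale_sd,
                               kappa_sd = kappa_sd),
                 n_cutpoints = 4L),
            class = "voi_model_spec")
}

#' Sampler configuration
#'
#' Defaults follow the study: 1000 iterations per chain of which 500 are
#' warmup, over 4 chains, retaining \code{(iterations - warmup) * chains =
#' 2000} posterior draws per parameter.
#'
#' @param iterations iterations per chain, warmup included.
#' @param warmup warmup (adaptation) iterations per chain.
#' @param chains number of chains, run sequentially.
#' @param seed integer seed; chain c uses \code{seed + c - 1}.
#' @param max_treedepth NUTS maximum tree depth.
#' @param adapt_delta dual-averaging target acceptance statistic.
#' @param init_radius uniform(-r, r) initialization on the unconstrained scale.
#' @return list of class \code{voi_sampler_config}.
#' @export
sampler_config <- function(iterations = 1000, warmup = 500, chains = 4,
                           seed = 1L, max_treedepth = 10, adapt_delta = 0.8,
                           init_radius = 1) {
  if (warmup >= iterations) stop("warmup must be < iterations")
  if (chains < 1) stop("need at least one chain")
  structure(list(iterations = as.integer(iterations),
                 warmup = as.integer(warmup), chains = as.integer(chains),
                 seed = as.integer(seed),
                 max_treedepth = as.integer(max_treedepth),
                 adapt_delta = adapt_delta, init_radius = init_radius,
                 retained = (as.integer(iterations) - as.integer(warmup)) *
                   as.integer(chains)),
            class = "voi_sampler_config")
}

# trial table -> 0-based data list for the C++ model
trials_to_standata <- function(trials) {
  need <- c("subject", "valence", "p", "cost_rank", "response")
  missing <- setdiff(need, names(trials))
  if (length(missing))
    stop("trial table missing columns: ", paste(missing, collapse = ", "))
  if (any(!trials$response %in% 1:5)) stop("responses must be in 1..5")
  check_scenarios(trials)
  subjects <- sort(unique(trials$subject))
  list(subj = as.integer(match(trials$subject, subjects) - 1L),
       y = as.integer(trials$response),
       gain = as.integer(trials$valence == "gain"),
       p = as.numeric(trials$p),
       crank = as.numeric(trials$cost_rank),
       n_subj = length(subjects),
       subjects = subjects)
}

# unconstrained parameter layout mirroring src/sampler.cpp (1-based)
param_layout <- function(spec, n_subj) {
  blk <- 3L + (!spec$shared_ci) + 2L * spec$scaling
  off <- 8L + spec$shared_ci
  within <- c(U_outcome = 1L, C_plan = 2L)
  if (!spec$shared_ci) {
    within["C_info"] <- 3L
    within["U_leisure"] <- 4L
  } else within["U_leisure"] <- 3L
  if (spec$scaling) {
    within["s_gain"] <- max(within) + 1L
    within["s_loss"] <- max(within) + 1L
  }
  list(mu = 1:4, kraw = 5:8,
       shared_ci = if (spec$shared_ci) 9L else integer(0),
       off = off, blk = blk, within = within, n_subj = n_subj)
}

#' Fit the hierarchical planning model
#'
#' Samples the posterior of the resource-rational planning model with the
#' package's No-U-Turn sampler (multinomial trajectory sampling,
#' dual-averaging step size, diagonal mass adaptation). The likelihood is
#' \code{response ~ OrderedLogistic(VOI, kappa)} with VOI computed from each
#' subject's parameters on each trial. Chains run sequentially and are seeded
#' \code{seed, seed + 1, ...}.
#'
#' @param trials trial table (see \code{\link{simulate_trials}}).
#' @param spec a \code{\link{model_spec}}.
#' @param cfg a \code{\link{sampler_config}}.
#' @return object of class \code{voi_fit}: constrained draws, per-subject
#'   posterior means, trial-level latent means (VOI, U_info, U_plan),
#'   convergence diagnostics, and sampler metadata. Warns when any split-Rhat
#'   exceeds 1.01.
#' @export
fit_model <- function(trials, spec = model_spec(), cfg = sampler_config()) {
  stopifnot(inherits(spec, "voi_model_spec"), inherits(cfg, "voi_sampler_config"))
  sd <- trials_to_standata(trials)
  if (min(table(sd$subj)) < 1) stop("every subject needs at least one trial")
  lay <- param_layout(spec, sd$n_subj)

  keep <- cfg$iterations - cfg$warmup
  raw <- vector("list", cfg$chains)
  divergent <- integer(0)
  treedepth <- integer(0)
  for (ch in seq_len(cfg$chains)) {
    set.seed(cfg$seed + ch - 1L)
    res <- nuts_chain(sd[c("subj", "y", "gain", "p", "crank", "n_subj")],
                      spec$scaling, spec$shared_ci, spec$priors,
                      cfg$iterations, cfg$warmup, cfg$init_radius,
                      cfg$max_treedepth, cfg$adapt_delta)
    raw[[ch]] <- res$draws
    divergent <- c(divergent, res$divergent)
    treedepth <- c(treedepth, res$treedepth)
  }
  un <- do.call(rbind, raw)
  chain_id <- rep(seq_len(cfg$chains), each = keep)

  # constrain
  S <- nrow(un)
  draws_mu <- un[, lay$mu, drop = FALSE]
  colnames(draws_mu) <- paste0("mu_", c("U_outcome", "C_plan", "C_info",
                                        "U_leisure"))
  kraw <- un[, lay$kraw, drop = FALSE]
  draws_kappa <- cbind(kraw[, 1],
                       kraw[, 1] + exp(kraw[, 2]),
                       kraw[, 1] + exp(kraw[, 2]) + exp(kraw[, 3]),
                       kraw[, 1] + exp(kraw[, 2]) + exp(kraw[, 3]) +
                         exp(kraw[, 4]))
  colnames(draws_kappa) <- paste0("kappa", 1:4)

  subj_par <- function(name) {
    if (name %in% c("s_gain", "s_loss") && !spec$scaling)
      return(matrix(1, S, sd$n_subj))
    if (name == "C_info" && spec$shared_ci) {
      x <- exp(un[, lay$shared_ci])
      return(matrix(x, S, sd$n_subj))
    }
    cols <- lay$off + (seq_len(sd$n_subj) - 1L) * lay$blk + lay$within[[name]]
    exp(un[, cols, drop = FALSE])
  }
  pars <- c("U_outcome", "C_plan", "C_info", "U_leisure", "s_gain", "s_loss")
  draws_subject <- lapply(stats::setNames(pars, pars), subj_par)

  subject_means <- data.frame(subject = sd$subjects)
  for (p in pars) subject_means[[p]] <- colMeans(draws_subject[[p]])

  fit <- structure(list(
    spec = spec, config = cfg, trials = trials, subjects = sd$subjects,
    standata = sd, chain_id = chain_id,
    draws_mu = draws_mu, draws_kappa = draws_kappa,
    draws_subject = draws_subject, subject_means = subject_means,
    divergent = divergent, treedepth = treedepth), class = "voi_fit")

  fit$trial_latents <- trial_latent_means(fit)
  mon <- rbind(
    data.frame(parameter = colnames(draws_mu),
               rhat = apply(draws_mu, 2, split_rhat, chain_id = chain_id),
               ess = apply(draws_mu, 2, ess_basic, chain_id = chain_id)),
    data.frame(parameter = colnames(draws_kappa),
               rhat = apply(draws_kappa, 2, split_rhat, chain_id = chain_id),
               ess = apply(draws_kappa, 2, ess_basic, chain_id = chain_id)))
  fit$diagnostics <- mon
  bad <- mon$parameter[is.finite(mon$rhat) & mon$rhat > 1.01]
  if (length(bad))
    warning("split-Rhat > 1.01 for: ", paste(bad, collapse = ", "))
  fit
}

# posterior draws of VOI / U_info / U_plan for each trial (S x T matrices)
trial_latent_draws <- function(fit, what = c("voi", "u_info", "u_plan")) {
  what <- match.arg(what)
  sd <- fit$standata
  ds <- fit$draws_subject
  S <- nrow(fit$draws_mu)
  Tn <- length(sd$y)
  out <- matrix(NA_real_, S, Tn)
  for (t in seq_len(Tn)) {
    j <- sd$subj[t] + 1L
    s <- if (sd$gain[t] == 1L) ds$s_gain[, j] else ds$s_loss[, j]
    uo <- ds$U_outcome[, j]; cp <- ds$C_plan[, j]
    ui <- sd$p[t] * (s * uo - cp) - ds$C_info[, j] * sd$crank[t]
    if (what == "u_info") { out[, t] <- ui; next }
    up <- sd$p[t] * s * uo - cp
    if (what == "u_plan") { out[, t] <- up; next }
    out[, t] <- ui - pmax(up, ds$U_leisure[, j])
  }
  out
}

trial_latent_means <- function(fit) {
  data.frame(subject = fit$trials$subject,
             voi = colMeans(trial_latent_draws(fit, "voi")),
             u_info = colMeans(trial_latent_draws(fit, "u_info")),
             u_plan = colMeans(trial_latent_draws(fit, "u_plan")))
}

#' @export
print.voi_fit <- function(x, ...) {
  cat("Hierarchical planning model fit (", x$spec$variant, ")\n", sep = "")
  cat(sprintf("  %d subjects, %d trials, %d retained draws (%d chains)\n",
              length(x$subjects), nrow(x$trials), nrow(x$draws_mu),
              x$config$chains))
  cat(sprintf("  divergent transitions: %d; max split-Rhat (mu, kappa): %.3f\n",
              sum(x$divergent), max(x$diagnostics$rhat, na.rm = TRUE)))
  invisible(x)
}

log1pexp <- function(x) {
  out <- x
  lo <- x < 33
  out[lo] <- log1p(exp(x[lo]))
  out
}

# stable log ordered-logistic pmf for a vector of latent draws at category y
ord_lpmf_draws <- function(y, eta, kappa) {
  if (y == 1) return(stats::plogis(kappa[, 1] - eta, log.p = TRUE))
  if (y == 5) return(stats::plogis(eta - kappa[, 4], log.p = TRUE))
  a <- kappa[, y - 1] - eta
  b <- kappa[, y] - eta
  -a - log1pexp(-a) - log1pexp(-b) + log1p(-exp(a - b))
}

#' Pointwise log-likelihood matrix
#'
#' Per-draw, per-trial log ordered-logistic likelihood of the observed
#' category given each draw's VOI and cut points — the input to PSIS-LOO.
#'
#' @param fit a \code{voi_fit}.
#' @param trials trial table; defaults to the fitted trials, and must match
#'   the fit's subjects and trial count otherwise.
#' @return draws x trials matrix of log-likelihoods.
#' @export
pointwise_loglik <- function(fit, trials = fit$trials) {
  sd2 <- trials_to_standata(trials)
  if (!identical(sd2$subjects, fit$standata$subjects) ||
      length(sd2$y) != length(fit$standata$y))
    stop("trial table does not match the fitted data")
  voi <- trial_latent_draws(fit, "voi")
  out <- matrix(NA_real_, nrow(voi), ncol(voi))
  for (t in seq_len(ncol(voi)))
    out[, t] <- ord_lpmf_draws(sd2$y[t], voi[, t], fit$draws_kappa)
  out
}
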