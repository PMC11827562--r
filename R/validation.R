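#' Posterior predictive dataset
#'
#' Pushes each subject's posterior-mean parameters through the trial
#' simulator on the full design grid — the standard overlay check that the
#' fitted model reproduces cell-level willingness-to-pay summaries.
#'
#' @param fit a \code{\link{fit_model}} result.
#' @param grid design grid (defaults to the study grid).
#' @param kappa cut points used for emission; defaults to the posterior mean
#'   cut points of the fit.
#' @param seed integer seed.
#' @return simulated trial table with one row per subject x scenario.
#' @export
posterior_predictive_dataset <- function(fit, grid = build_design_grid(),
                                         kappa = NULL, seed = 1L) {
  stopifnot(inherits(fit, "voi_fit"))
  if (is.null(kappa)) kappa <- cut_points(colMeans(fit$draws_kappa))
  sm <- fit$subject_means
  agents <- agent_params(sm$U_outcome, sm$C_plan, sm$C_info, sm$U_leisure,
                         sm$s_gain, sm$s_loss)
  agents$subject <- sm$subject
  simulate_trials(agents, grid, kappa, seed = seed)
}

#' Parameter-recovery report
#'
#' Refits the model to trials simulated from known agents and reports the
#' Pearson correlation between ground-truth and recovered (posterior-mean)
#' parameters, with a bootstrap confidence interval over subjects.
#'
#' @param truth \code{voi_agents} used to simulate \code{trials}.
#' @param trials trial table simulated from \code{truth}.
#' @param spec,cfg model and sampler configuration for the refit.
#' @param n_boot bootstrap resamples of subjects (default 1000).
#' @param boot_seed seed for the bootstrap resampling.
#' @return object of class \code{voi_recovery}: per-parameter \code{r} with
#'   95\% CI, a \code{degenerate} flag for zero-variance truths, and the
#'   underlying fit.
#' @export
recover_parameters <- function(truth, trials, spec = model_spec(),
                               cfg = sampler_config(), n_boot = 1000,
                               boot_seed = 1L) {
  validate_agents(truth)
  if (is.null(truth$subject)) truth$subject <- seq_len(nrow(truth))
  fit <- fit_model(trials, spec, cfg)
  est <- fit$subject_means
  truth <- truth[match(est$subject, truth$subject), , drop = FALSE]
  pars <- c("U_outcome", "C_plan", "C_info", "U_leisure", "s_gain", "s_loss")
  n <- nrow(est)
  set.seed(boot_seed)
  boot_idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), n, n_boot)
  rows <- lapply(pars, function(p) {
    x <- truth[[p]]; y <- est[[p]]
    degenerate <- stats::sd(x) == 0 || stats::sd(y) == 0
    if (degenerate)
      return(data.frame(parameter = p, r = NA_real_, ci_lower = NA_real_,
                        ci_upper = NA_real_, degenerate = TRUE))
    r <- stats::cor(x, y)
    br <- apply(boot_idx, 2, function(i) {
      if (stats::sd(x[i]) == 0 || stats::sd(y[i]) == 0) NA_real_
      else stats::cor(x[i], y[i])
    })
    ci <- stats::quantile(br, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
    data.frame(parameter = p, r = r, ci_lower = ci[1], ci_upper = ci[2],
               degenerate = FALSE)
  })
  structure(list(report = do.call(rbind, rows), n_subjects = n,
                 n_boot = n_boot, fit = fit),
            class = "voi_recovery")
}

#' @export
print.voi_recovery <- function(x, ...) {
  cat("Parameter recovery (", x$n_subjects, " subjects):\n", sep = "")
  print(x$report, row.names = FALSE)
  invisible(x)
}
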