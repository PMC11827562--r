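test_that("model and sampler configurations enforce the study structure", {
  expect_identical(sampler_config()$retained, 2000L)
  expect_error(sampler_config(iterations = 400, warmup = 500), "warmup")
  expect_identical(model_spec("no_scaling")$scaling, FALSE)
  expect_identical(model_spec("shared_Cinfo")$shared_ci, TRUE)
  expect_error(model_spec("bogus"))
})

test_that("model log-likelihood matches the voi_core emission law exactly", {
  # likelihood oracle: for fixed parameters the C++ model's log posterior
  # difference across responses equals the ordered-logistic log pmf from
  # likert_probabilities (priors cancel)
  st <- small_study()
  sd <- voiplan:::trials_to_standata(st$trials)
  dat <- sd[c("subj", "y", "gain", "p", "crank", "n_subj")]
  spec <- model_spec("full")
  d <- voiplan:::hier_dim(dat, spec$scaling, spec$shared_ci, spec$priors)
  set.seed(111)
  th <- rnorm(d, 0, 0.4)
  lp_at <- function(dat) voiplan:::hier_logp_grad(th, dat, spec$scaling,
                                                  spec$shared_ci,
                                                  spec$priors)$logp
  base <- lp_at(dat)
  # decode theta into agents/kappa via the package layout and compare on 100
  # random trials
  lay <- voiplan:::param_layout(spec, sd$n_subj)
  kraw <- th[lay$kraw]
  kappa <- cumsum(c(kraw[1], exp(kraw[2:4])))
  set.seed(112)
  cells <- sample(length(dat$y), 100)
  for (t in cells) {
    j <- dat$subj[t] + 1L
    o <- lay$off + (j - 1L) * lay$blk
    ag <- agent_params(exp(th[o + lay$within[["U_outcome"]]]),
                       exp(th[o + lay$within[["C_plan"]]]),
                       exp(th[o + lay$within[["C_info"]]]),
                       exp(th[o + lay$within[["U_leisure"]]]),
                       exp(th[o + lay$within[["s_gain"]]]),
                       exp(th[o + lay$within[["s_loss"]]]))
    sc <- data.frame(valence = ifelse(dat$gain[t] == 1, "gain", "loss"),
                     p = dat$p[t], cost_rank = dat$crank[t])
    pr <- likert_probabilities(value_of_information(ag, sc),
                               cut_points(kappa))[1, ]
    # switch the observed response and compare log-posterior deltas
    alt <- if (dat$y[t] == 1L) 2L else 1L
    dat2 <- dat
    dat2$y[t] <- alt
    expect_equal(base - lp_at(dat2), log(pr[dat$y[t]]) - log(pr[alt]),
                 ignore_attr = TRUE, tolerance = 1e-10)
  }
})

test_that("reduced-model nesting: no_scaling equals full at s = 1", {
  st <- small_study()
  sd <- voiplan:::trials_to_standata(st$trials)
  dat <- sd[c("subj", "y", "gain", "p", "crank", "n_subj")]
  full <- model_spec("full")
  red <- model_spec("no_scaling")
  d_red <- voiplan:::hier_dim(dat, red$scaling, red$shared_ci, red$priors)
  set.seed(121)
  th_red <- rnorm(d_red, 0, 0.4)
  lay_f <- voiplan:::param_layout(full, sd$n_subj)
  lay_r <- voiplan:::param_layout(red, sd$n_subj)
  # embed: same subject parameters, s_gain = s_loss = 1 (log = 0)
  th_full <- numeric(voiplan:::hier_dim(dat, full$scaling, full$shared_ci,
                                        full$priors))
  th_full[1:8] <- th_red[1:8]
  for (j in seq_len(sd$n_subj)) {
    of <- lay_f$off + (j - 1L) * lay_f$blk
    or <- lay_r$off + (j - 1L) * lay_r$blk
    for (nm in names(lay_r$within))
      th_full[of + lay_f$within[[nm]]] <- th_red[or + lay_r$within[[nm]]]
  }
  lp_f <- voiplan:::hier_logp_grad(th_full, dat, TRUE, FALSE, full$priors)$logp
  lp_r <- voiplan:::hier_logp_grad(th_red, dat, FALSE, FALSE, red$priors)$logp
  # identical likelihood; the full model adds only the s-prior and Jacobian
  # terms at s = 1 (constant in the data): difference must be data-free
  n_s <- 2 * sd$n_subj
  # truncated-normal s prior at s = 1: log density minus log Phi(1); jac = 0
  const <- n_s * (dnorm(1, 1, 1, log = TRUE) -
                    pnorm(1, log.p = TRUE))
  expect_equal(lp_f - lp_r, const, tolerance = 1e-8)
  # and it stays the same constant for different data
  dat2 <- dat
  dat2$y <- rev(dat2$y)
  lp_f2 <- voiplan:::hier_logp_grad(th_full, dat2, TRUE, FALSE,
                                    full$priors)$logp
  lp_r2 <- voiplan:::hier_logp_grad(th_red, dat2, FALSE, FALSE,
                                    red$priors)$logp
  expect_equal(lp_f2 - lp_r2, lp_f - lp_r, tolerance = 1e-10)
})

test_that("fit_model returns the configured draws and positive parameters", {
  fit <- small_fit()
  expect_s3_class(fit, "voi_fit")
  expect_identical(nrow(fit$draws_mu), 600L)   # (600 - 300) x 2 chains
  expect_identical(ncol(fit$draws_kappa), 4L)
  expect_true(all(diff(t(fit$draws_kappa)) > 0))      # ordered in every draw
  for (p in names(fit$draws_subject))
    expect_true(all(fit$draws_subject[[p]] > 0))
  expect_identical(sampler_config()$retained, 2000L)
  expect_true(all(c("rhat", "ess") %in% names(fit$diagnostics)))
})

test_that("a subject answering only 'no preference' pins VOI between the
           middle cut points", {
  grid <- build_design_grid()
  trials <- data.frame(subject = 1L, grid, response = 3L)
  fit <- suppressWarnings(
    fit_model(trials, model_spec("no_scaling"),
              sampler_config(iterations = 400, warmup = 200, chains = 2,
                             seed = 9)))
  voi_mean <- fit$trial_latents$voi
  k2 <- mean(fit$draws_kappa[, 2])
  k3 <- mean(fit$draws_kappa[, 3])
  expect_gt(mean(voi_mean > k2 & voi_mean < k3), 0.9)
})

test_that("pointwise_loglik is coherent and matches independent recomputation", {
  fit <- small_fit()
  ll <- pointwise_loglik(fit)
  expect_identical(dim(ll), c(600L, nrow(fit$trials)))
  expect_true(all(ll < 0))

  # category normalization: summing probabilities over all 5 categories = 1
  t_idx <- c(1L, 57L, 200L)
  for (t in t_idx) {
    tot <- rowSums(vapply(1:5, function(k) {
      tr2 <- fit$trials
      tr2$response[t] <- k
      exp(pointwise_loglik(fit, tr2)[, t])
    }, numeric(600)))
    expect_equal(tot, rep(1, 600), tolerance = 1e-10)
  }

  # oracle: recompute 100 random cells from the draws via voi_core
  set.seed(131)
  cells <- cbind(sample(600, 100, TRUE), sample(nrow(fit$trials), 100, TRUE))
  for (i in seq_len(nrow(cells))) {
    s <- cells[i, 1]; t <- cells[i, 2]
    tr <- fit$trials[t, ]
    j <- match(tr$subject, fit$subjects)
    ag <- agent_params(fit$draws_subject$U_outcome[s, j],
                       fit$draws_subject$C_plan[s, j],
                       fit$draws_subject$C_info[s, j],
                       fit$draws_subject$U_leisure[s, j],
                       fit$draws_subject$s_gain[s, j],
                       fit$draws_subject$s_loss[s, j])
    pr <- likert_probabilities(value_of_information(ag, tr),
                               cut_points(fit$draws_kappa[s, ]))
    expect_equal(ll[s, t], log(pr[1, tr$response]), ignore_attr = TRUE,
                 tolerance = 1e-10)
  }
  expect_error(pointwise_loglik(fit, fit$trials[-1, ]), "does not match")
})

test_that("prior-predictive draws reach all five Likert categories", {
  set.seed(141)
  reps <- 300
  cats <- integer(0)
  for (r in seq_len(reps)) {
    mu <- rnorm(4, 0, 5)
    ag <- agent_params(voiplan:::rtruncnorm0(1, mu[1], 1),
                       voiplan:::rtruncnorm0(1, mu[2], 1),
                       voiplan:::rtruncnorm0(1, mu[3], 1),
                       voiplan:::rtruncnorm0(1, mu[4], 1),
                       voiplan:::rtruncnorm0(1, 1, 1),
                       voiplan:::rtruncnorm0(1, 1, 1))
    kap <- cut_points(sort(rnorm(4, 0, 10), decreasing = FALSE) +
                        c(0, 1e-6, 2e-6, 3e-6))
    sc <- build_design_grid()[sample(30, 3), ]
    pr <- likert_probabilities(value_of_information(ag, sc), kap)
    cats <- union(cats, which(colSums(pr) > 1e-6))
  }
  expect_setequal(cats, 1:5)
})

test_that("degenerate data fail loudly", {
  expect_error(fit_model(data.frame(subject = 1, valence = "gain", p = 0.5,
                                    cost_rank = 0, response = 7)),
               "1..5")
})
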