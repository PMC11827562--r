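test_that("posterior predictive dataset mirrors the fitted subjects", {
  sf <- study_fit()
  ppc <- posterior_predictive_dataset(sf$fit, seed = 411)
  expect_identical(nrow(ppc), 40L * 30L)
  expect_identical(sort(unique(ppc$subject)), sf$fit$subjects)
  expect_true(all(table(ppc$subject, ppc$scenario) == 1))

  # determinism: same seed, same dataset; explicit kappa equals the default
  ppc2 <- posterior_predictive_dataset(
    sf$fit, kappa = cut_points(colMeans(sf$fit$draws_kappa)), seed = 411)
  expect_identical(ppc, ppc2)

  # the function is simulate_trials at the posterior means: a collapsed
  # "posterior" (single repeated draw) gives the identical dataset
  sm <- sf$fit$subject_means
  ag <- agent_params(sm$U_outcome, sm$C_plan, sm$C_info, sm$U_leisure,
                     sm$s_gain, sm$s_loss)
  ag$subject <- sm$subject
  direct <- simulate_trials(ag, build_design_grid(),
                            cut_points(colMeans(sf$fit$draws_kappa)),
                            seed = 411)
  expect_identical(ppc$response, direct$response)
})

test_that("PPC marginal means reproduce the qualitative behavioural
           orderings", {
  sf <- study_fit()
  # average several PPC replicates to remove single-dataset emission noise
  cells <- Reduce(`+`, lapply(1:10, function(k) {
    summarize_willingness(
      posterior_predictive_dataset(sf$fit, seed = 420 + k))$mean_score
  })) / 10
  obs <- summarize_willingness(sf$trials)

  # decreasing in cost, inherited from VOI through the emission
  ppc_cost <- tapply(cells, obs$cost_dollars, mean)
  expect_true(all(diff(ppc_cost[order(as.numeric(names(ppc_cost)))]) < 0))
  # rising with probability below the population-typical kink (p* ~ 0.5)
  ppc_p <- tapply(cells, obs$p, mean)
  ppc_p <- ppc_p[order(as.numeric(names(ppc_p)))]
  expect_true(all(diff(ppc_p[1:3]) > 0))
  # planted gain seeking (s_gain mean > s_loss mean) survives fit + PPC
  agents <- sample_agents(population_config(15, scale_mean_gain = 1.8,
                                            scale_mean_loss = 0.6,
                                            seed = 471))
  trials <- simulate_trials(agents, build_design_grid(), seed = 472)
  fit <- suppressWarnings(
    fit_model(trials, model_spec("full"),
              sampler_config(iterations = 400, warmup = 200, chains = 2,
                             seed = 473)))
  # expected display score under the emission at the posterior means
  # (noise-free version of a PPC dataset average)
  sm <- fit$subject_means
  kap <- cut_points(colMeans(fit$draws_kappa))
  grid <- build_design_grid()
  ag <- agent_params(sm$U_outcome, sm$C_plan, sm$C_info, sm$U_leisure,
                     sm$s_gain, sm$s_loss)
  ed <- numeric(0); val <- character(0)
  for (i in seq_len(nrow(sm))) {
    pr <- likert_probabilities(
      value_of_information(ag[i, , drop = FALSE], grid), kap)
    ed <- c(ed, as.numeric(pr %*% (-2:2)))
    val <- c(val, grid$valence)
  }
  by_val <- tapply(ed, val, mean)
  expect_gt(by_val[["gain"]], by_val[["loss"]])
  # the fit preserves the planted direction of the scaling asymmetry
  expect_gt(mean(sm$s_gain), mean(sm$s_loss))
})

test_that("recover_parameters flags degenerate truth variance", {
  truth <- agent_params(rep(1.5, 5), rep(0.8, 5), rep(0.1, 5), rep(0.25, 5))
  truth$subject <- 1:5
  trials <- simulate_trials(truth, build_design_grid(), seed = 431)
  rec <- suppressWarnings(
    recover_parameters(truth, trials, model_spec("no_scaling"),
                       sampler_config(iterations = 300, warmup = 150,
                                      chains = 2, seed = 432),
                       n_boot = 50))
  expect_true(all(rec$report$degenerate))
  expect_true(all(is.na(rec$report$r)))
})

test_that("bootstrap CIs bracket the point estimate and behave under
           replication (scaled down)", {
  # scaled-down coverage probe: replicate small recoveries and check the
  # bootstrap CI contains the replicate-median r for well-identified
  # parameters
  reps <- 6
  rs <- matrix(NA_real_, reps, 2,
               dimnames = list(NULL, c("C_info", "U_leisure")))
  cis <- vector("list", reps)
  for (k in seq_len(reps)) {
    agents <- sample_agents(population_config(15, seed = 440 + k))
    trials <- simulate_trials(agents, build_design_grid(), seed = 460 + k)
    rec <- suppressWarnings(
      recover_parameters(agents, trials, model_spec("full"),
                         sampler_config(iterations = 500, warmup = 250,
                                        chains = 2, seed = 480 + k),
                         n_boot = 400, boot_seed = k))
    rep_tab <- rec$report
    rownames(rep_tab) <- rep_tab$parameter
    rs[k, ] <- rep_tab[colnames(rs), "r"]
    cis[[k]] <- rep_tab[colnames(rs), c("ci_lower", "ci_upper")]
    expect_true(all(rep_tab$ci_lower <= rep_tab$r &
                      rep_tab$r <= rep_tab$ci_upper, na.rm = TRUE))
  }
  med <- apply(rs, 2, stats::median)
  hits <- vapply(seq_len(reps), function(k)
    sum(cis[[k]]$ci_lower <= med & med <= cis[[k]]$ci_upper), 0)
  expect_gte(sum(hits) / (reps * 2), 0.75)
})

test_that("generative self-consistency: hyper-mean coverage (scaled down)", {
  # fit the model to its own generative world; population hyper-means should
  # fall inside the posterior 95% intervals most of the time
  reps <- 6
  mu_true <- c(3, 0.8, 0.1, 0.25)
  hits <- 0
  for (k in seq_len(reps)) {
    agents <- sample_agents(population_config(12, seed = 500 + k))
    trials <- simulate_trials(agents, build_design_grid(), seed = 520 + k)
    fit <- suppressWarnings(
      fit_model(trials, model_spec("full"),
                sampler_config(iterations = 500, warmup = 250, chains = 2,
                               seed = 540 + k)))
    qs <- apply(fit$draws_mu, 2, stats::quantile, c(0.025, 0.975))
    hits <- hits + sum(qs[1, ] <= mu_true & mu_true <= qs[2, ])
  }
  expect_gte(hits / (reps * 4), 0.80)
})
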