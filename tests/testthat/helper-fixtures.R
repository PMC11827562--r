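# Shared fixtures: small, generated in code, fixed seeds.

fig3_agent <- function() {
  agent_params(U_outcome = 1.5, C_plan = 0.8, C_info = 0.1, U_leisure = 0.25)
}

fig3_scenarios <- function(p, cost_rank = 1, valence = "gain") {
  data.frame(valence = valence, p = p, cost_rank = cost_rank)
}

small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      agents <- sample_agents(population_config(12, seed = 301))
      trials <- simulate_trials(agents, build_design_grid(), seed = 302)
      cache <<- list(agents = agents, trials = trials)
    }
    cache
  }
})

# one shared small-scale fit reused across inference tests (~15 s)
small_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      st <- small_study()
      cache <<- suppressWarnings(
        fit_model(st$trials, model_spec("full"),
                  sampler_config(iterations = 600, warmup = 300, chains = 2,
                                 seed = 303)))
    }
    cache
  }
})

random_agents <- function(n, seed) {
  set.seed(seed)
  agent_params(U_outcome = runif(n, 0.2, 3), C_plan = runif(n, 0.2, 2),
               C_info = runif(n, 0.05, 1.5), U_leisure = runif(n, 0.05, 1.5),
               s_gain = runif(n, 0.3, 2), s_loss = runif(n, 0.3, 2))
}

random_scenarios <- function(n, seed) {
  set.seed(seed)
  data.frame(valence = sample(c("gain", "loss"), n, TRUE),
             p = runif(n, 0.01, 0.99),
             cost_rank = sample(0:2, n, TRUE))
}

# brute-force VOI oracle: enumerate the three choices explicitly
voi_oracle <- function(agent, sc) {
  vapply(seq_len(nrow(sc)), function(i) {
    a <- agent[min(i, nrow(agent)), ]
    s <- if (sc$valence[i] == "gain") a$s_gain else a$s_loss
    u_info <- sc$p[i] * (s * a$U_outcome - a$C_plan) - a$C_info * sc$cost_rank[i]
    u_plan <- sc$p[i] * s * a$U_outcome - a$C_plan
    u_deny <- a$U_leisure
    u_info - max(u_plan, u_deny)
  }, 0)
}

# study-scale fixture for validation + acceptance: 40 subjects x 30 trials
# fitted with the study sampler settings (4 chains, 500 warmup / 1000 iter);
# computed once and reused across test files
study_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      agents <- sample_agents(population_config(40, seed = 401))
      trials <- simulate_trials(agents, build_design_grid(), seed = 402)
      fit <- suppressWarnings(
        fit_model(trials, model_spec("full"), sampler_config(seed = 403)))
      cache <<- list(agents = agents, trials = trials, fit = fit)
    }
    cache
  }
})

null_scores <- function(subjects, seed) {
  set.seed(seed)
  data.frame(subject = subjects,
             somatic = rnorm(length(subjects)),
             cognitive = rnorm(length(subjects)),
             negative_affect = rnorm(length(subjects)),
             low_self_esteem = rnorm(length(subjects)))
}
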