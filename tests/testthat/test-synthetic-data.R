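test_that("sample_agents draws exact truncated normals, reproducibly", {
  cfg <- population_config(10, seed = 5)
  expect_identical(sample_agents(cfg), sample_agents(cfg))

  # near-degenerate SD: agents collapse onto positive population means
  cfg0 <- population_config(5, sd_subject = 1e-12, scale_sd = 1e-12, seed = 1)
  a0 <- sample_agents(cfg0)
  expect_equal(a0$U_outcome, rep(3, 5), tolerance = 1e-6)
  expect_equal(a0$U_leisure, rep(0.25, 5), tolerance = 1e-6)

  # large-sample mean matches the closed-form truncated-normal mean
  big <- sample_agents(population_config(10000, mu_U_outcome = 2, seed = 7))
  m_theory <- voiplan:::truncnorm0_mean(2, 1)
  expect_equal(m_theory, 2.055, tolerance = 1e-3)
  se <- sd(big$U_outcome) / sqrt(10000)
  expect_lt(abs(mean(big$U_outcome) - m_theory), 3 * se)
  expect_true(all(as.matrix(big[1:6]) > 0))
})

test_that("design grid is the full factorial with study defaults of 30", {
  g <- build_design_grid()
  expect_identical(nrow(g), 30L)
  expect_identical(nrow(unique(g[c("valence", "p", "cost_dollars")])), 30L)
  expect_setequal(g$cost_rank, 0:2)
  expect_identical(nrow(build_design_grid(0.5, 0, "gain")), 1L)
  expect_identical(nrow(build_design_grid(costs = c(0, 5))), 20L)
  expect_error(build_design_grid(probabilities = c(0.5, 0.5)), "duplicate")
})

test_that("simulate_trials covers the grid and matches its emission law", {
  st <- small_study()
  trials <- st$trials
  expect_identical(nrow(trials), 12L * 30L)
  counts <- table(trials$subject, trials$scenario)
  expect_true(all(counts == 1))
  expect_true(all(trials$response %in% 1:5))
  expect_identical(trials$display_score, trials$response - 3L)
  expect_identical(simulate_trials(st$agents, build_design_grid(), seed = 302),
                   trials)

  # huge C_info with nonzero cost: VOI -> -inf, responses pile on category 1
  denial <- agent_params(1, 1, 1e6, 0.5)
  tr <- simulate_trials(denial, build_design_grid(), seed = 1)
  expect_true(all(tr$response[tr$cost_rank > 0] == 1L))

  # empirical category frequencies match likert_probabilities (binomial bound)
  a <- fig3_agent()
  sc <- data.frame(valence = "gain", p = 0.7, cost_rank = 1)
  kap <- default_cutpoints()
  pr <- likert_probabilities(value_of_information(a, sc), kap)[1, ]
  reps <- simulate_trials(a[rep(1, 10000), ], sc, kap, seed = 9)
  freq <- tabulate(reps$response, 5) / 10000
  bound <- 3 * sqrt(pr * (1 - pr) / 10000)
  expect_true(all(abs(freq - pr) <= bound + 1e-12))
})

test_that("planted factor scores reproduce the configured linear map", {
  agents <- sample_agents(population_config(500, seed = 41))
  # noiseless identity-like map: somatic tracks -C_info exactly in rank
  B <- matrix(0, 7, 4)
  B[3, 1] <- -1
  pl <- planted_association(B, residual_sd = 1e-9)
  sc <- simulate_factor_scores(agents, pl, seed = 42)
  expect_equal(cor(sc$somatic, agents$C_info), -1, tolerance = 1e-6)

  # zero map: pure noise, no association with any parameter
  pl0 <- planted_association(matrix(0, 7, 4))
  sc0 <- simulate_factor_scores(agents, pl0, seed = 43)
  for (p in c("U_outcome", "C_plan", "C_info", "U_leisure"))
    expect_lt(abs(cor(sc0$somatic, agents[[p]])), 3 / sqrt(500))

  # default pattern: signed associations present in the configured cells
  scd <- simulate_factor_scores(agents, planted_association(), seed = 44)
  expect_lt(cor(scd$somatic, agents$C_info), 0)
  expect_gt(cor(scd$somatic, agents$U_leisure), 0)
  expect_gt(cor(scd$negative_affect, agents$C_info), 0)
})

test_that("simulated questionnaires discretize and reverse as specified", {
  agents <- sample_agents(population_config(400, seed = 51))
  scores <- simulate_factor_scores(agents, seed = 52)
  q <- simulate_questionnaires(scores, seed = 53)
  expect_identical(nrow(q), 400L * 41L)
  expect_true(all(q$response %in% 1:4))
  expect_identical(sum(q$inventory == "STAIT"), 400L * 20L)

  # zero factors, symmetric thresholds: items symmetric about 2.5
  null_scores <- data.frame(subject = 1:2000,
                            somatic = 0, cognitive = 0,
                            negative_affect = 0, low_self_esteem = 0)
  q0 <- simulate_questionnaires(null_scores, seed = 54)
  expect_lt(abs(mean(q0$response) - 2.5), 0.02)

  # reverse-coded STAIT items are emitted anxiety-absent: a subject with very
  # high negative affect (which loads on the reverse set in the synthetic
  # loading layout) records LOW raw responses there
  hi <- data.frame(subject = 1, somatic = 0, cognitive = 0,
                   negative_affect = 8, low_self_esteem = 0)
  qh <- simulate_questionnaires(hi, seed = 55)
  rev_rows <- qh$inventory == "STAIT" & qh$item_index %in% stait_reverse_items()
  expect_true(all(qh$response[rev_rows] == 1))
  expect_error(simulate_questionnaires(scores, thresholds = matrix(0, 2, 3)),
               "41 x 3")
})

test_that("questionnaire round trip recovers the planted factors", {
  agents <- sample_agents(population_config(500, seed = 61))
  scores <- simulate_factor_scores(agents, seed = 62)
  q <- simulate_questionnaires(scores, seed = 63)
  rec <- bartlett_scores(code_items(q), default_loading_config())
  rec <- rec[match(scores$subject, rec$subject), ]
  for (f in factor_names())
    expect_gt(cor(scores[[f]], rec[[f]]), 0.8)
})

test_that("population config validates its inputs", {
  expect_error(population_config(0), ">= 1")
  expect_error(population_config(5, sd_subject = 0), "> 0")
})
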