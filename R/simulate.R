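#' Population configuration for synthetic agent sampling
#'
#' The generative population mirrors the hierarchical prior structure of the
#' fitted model: the four utility/cost parameters are drawn per subject from
#' normals with SD \code{sd_subject} (fixed at 1 in the study) around
#' population means, truncated to be strictly positive; the outcome scalings
#' are drawn from a truncated \code{N(scale_mean, scale_sd)} (study values
#' 1, 1). Because truncation at 0 inflates the realized means (a
#' \code{N(0.25, 1)} lower-bounded at 0 has mean 0.89, not 0.25), the default
#' hyper-means are chosen so that the population-typical agent — the agent at
#' the truncated means — reproduces the worked-example regime structure: a
#' regime kink \code{p* = (U_leisure + C_plan) / (s U_outcome)} well inside
#' (0, 1) and the characteristic inverted-U value of information over
#' probability. With \code{mu_U_outcome = 3} the typical agent has
#' \code{p* ~ 0.5}; both the planning and the leisure regime are visited
#' across the probability levels of the design, which is what identifies
#' \code{U_outcome} and \code{C_plan} separately from the probability slopes.
#'
#' @param n_subjects number of agents to draw (>= 1).
#' @param mu_U_outcome,mu_C_plan,mu_C_info,mu_U_leisure population means.
#' @param sd_subject between-subject SD (study value 1).
#' @param scale_mean,scale_sd mean/SD for \code{s_gain} and \code{s_loss}.
#' @param scale_mean_gain,scale_mean_loss optional valence-specific scaling
#'   means (default \code{scale_mean}); set them apart to plant systematic
#'   gain seeking or loss aversion.
#' @param seed integer seed used by \code{\link{sample_agents}}.
#' @return list of class \code{voi_population}.
#' @export
population_config <- function(n_subjects,
                              mu_U_outcome = 3, mu_C_plan = 0.8,
                              mu_C_info = 0.1, mu_U_leisure = 0.25,
                              sd_subject = 1, scale_mean = 1, scale_sd = 1,
                              scale_mean_gain = scale_mean,
                              scale_mean_loss = scale_mean,
                              seed = 1L) {
  if (!is.numeric(n_subjects) || length(n_subjects) != 1 || n_subjects < 1)
    stop("n_subjects must be a single count >= 1")
  if (sd_subject <= 0 || scale_sd <= 0) stop("SDs must be > 0")
  structure(list(n_subjects = as.integer(n_subjects),
                 mu = c(U_outcome = mu_U_outcome, C_plan = mu_C_plan,
                        C_info = mu_C_info, U_leisure = mu_U_leisure),
                 sd_subject = sd_subject,
                 scale_mean = scale_mean, scale_sd = scale_sd,
                 scale_mean_gain = scale_mean_gain,
                 scale_mean_loss = scale_mean_loss,
                 seed = as.integer(seed)),
            class = "voi_population")
}

# exact truncated-normal sampling (lower bound 0) by inverse CDF on the
# upper tail: exact, seed-stable (unlike rejection), and accurate even when
# the untruncated mean sits far below 0
rtruncnorm0 <- function(n, mean, sd) {
  q <- stats::pnorm(0, mean, sd, lower.tail = FALSE)   # P(X > 0)
  u <- pmax(q * (1 - stats::runif(n)), .Machine$double.xmin)
  stats::qnorm(u, mean, sd, lower.tail = FALSE)
}

# mean of N(mean, sd) truncated to (0, Inf)
truncnorm0_mean <- function(mean, sd) {
  a <- -mean / sd
  mean + sd * stats::dnorm(a) / (1 - stats::pnorm(a))
}

#' Sample a synthetic agent population
#'
#' Each parameter is drawn independently from its (exactly) truncated normal
#' via the inverse-CDF transform, so draws are reproducible under the
#' configuration seed and remain strictly positive.
#'
#' @param cfg a \code{\link{population_config}}.
#' @return \code{voi_agents} data frame with \code{cfg$n_subjects} rows and a
#'   \code{subject} id column stored in row order.
#' @export
sample_agents <- function(cfg) {
  stopifnot(inherits(cfg, "voi_population"))
  n <- cfg$n_subjects
  set.seed(cfg$seed)
  a <- agent_params(
    U_outcome = rtruncnorm0(n, cfg$mu[["U_outcome"]], cfg$sd_subject),
    C_plan    = rtruncnorm0(n, cfg$mu[["C_plan"]], cfg$sd_subject),
    C_info    = rtruncnorm0(n, cfg$mu[["C_info"]], cfg$sd_subject),
    U_leisure = rtruncnorm0(n, cfg$mu[["U_leisure"]], cfg$sd_subject),
    s_gain    = rtruncnorm0(n, cfg$scale_mean_gain, cfg$scale_sd),
    s_loss    = rtruncnorm0(n, cfg$scale_mean_loss, cfg$scale_sd))
  a$subject <- seq_len(n)
  a
}

#' Full-factorial scenario design grid
#'
#' Crosses outcome valence, outcome probability, and dollar cost of
#' information; the study defaults give the 2 x 5 x 3 = 30-scenario grid
#' (win/lose $1000; probability 1, 10, 50, 90, 99\%; cost $0, $5, $100).
#'
#' @param probabilities probabilities of the outcome at 1 hour, in (0, 1).
#' @param costs dollar costs; rank-transformed into \code{cost_rank}.
#' @param valences subset of \code{c("gain", "loss")}.
#' @param magnitude outcome magnitude in dollars (design constant).
#' @return data frame with one row per scenario: \code{scenario}, \code{valence},
#'   \code{magnitude}, \code{p}, \code{cost_dollars}, \code{cost_rank}.
#' @export
build_design_grid <- function(probabilities = c(0.01, 0.10, 0.50, 0.90, 0.99),
                              costs = c(0, 5, 100),
                              valences = c("gain", "loss"),
                              magnitude = 1000) {
  if (!length(probabilities) || !length(costs) || !length(valences))
    stop("level sets must be nonempty")
  if (anyDuplicated(probabilities) || anyDuplicated(costs) ||
      anyDuplicated(valences))
    stop("duplicate levels in design grid")
  if (any(probabilities <= 0 | probabilities >= 1))
    stop("probabilities must lie strictly in (0, 1)")
  g <- expand.grid(valence = valences, p = probabilities, cost_dollars = costs,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$magnitude <- magnitude
  g$cost_rank <- rank_transform_cost(g$cost_dollars, sort(costs))
  g$scenario <- seq_len(nrow(g))
  g[c("scenario", "valence", "magnitude", "p", "cost_dollars", "cost_rank")]
}

#' Simulate a trial table of Likert responses
#'
#' For every subject x scenario cell, draws one Likert category from the
#' ordered-logistic response distribution at that agent's value of
#' information.
#'
#' @param agents \code{voi_agents} (one row per subject; a \code{subject}
#'   column is added if absent).
#' @param grid design grid from \code{\link{build_design_grid}}.
#' @param kappa cut points (see \code{\link{cut_points}}); default
#'   \code{c(-1.5, -0.5, 0.5, 1.5)}, symmetric on the VOI scale.
#' @param seed integer seed.
#' @return long-format \code{TrialTable} data frame: \code{subject},
#'   \code{scenario}, design columns, \code{response} (1..5) and
#'   \code{display_score} (-2..2).
#' @export
simulate_trials <- function(agents, grid, kappa = default_cutpoints(),
                            seed = 1L) {
  validate_agents(agents)
  check_scenarios(grid)
  kappa <- cut_points(unclass(kappa))
  if (is.null(agents$subject)) agents$subject <- seq_len(nrow(agents))
  set.seed(seed)
  n_sub <- nrow(agents)
  rows <- vector("list", n_sub)
  ncat <- length(kappa) + 1
  for (i in seq_len(n_sub)) {
    voi <- value_of_information(agents[i, , drop = FALSE], grid)
    pr <- likert_probabilities(voi, kappa)
    u <- stats::runif(nrow(grid))
    resp <- rowSums(u > t(apply(pr, 1, cumsum))) + 1L
    resp <- pmin(resp, ncat)
    rows[[i]] <- data.frame(subject = agents$subject[i], grid,
                            response = as.integer(resp))
  }
  out <- do.call(rbind, rows)
  out$display_score <- likert_display_score(out$response)
  rownames(out) <- NULL
  out
}

#' Default simulation cut points
#'
#' Placed at the quintiles of the default population's VOI distribution over
#' the 30-scenario grid, so simulated responses use all five Likert
#' categories about equally — mirroring full use of the scale in the task.
#'
#' @return the package's default cut points on the VOI scale.
#' @export
default_cutpoints <- function() cut_points(c(-2.3, -1.4, -0.7, -0.1))
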