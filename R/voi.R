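#' Agent parameters for the resource-rational planning model
#'
#' Constructs a validated table of per-subject parameters. All parameters are
#' utilities (unitless) and must be strictly positive: \code{U_outcome}, the
#' utility gained by having planned for an outcome that occurs; \code{C_plan},
#' the cognitive cost of planning; \code{C_info}, the utility cost of
#' information per rank unit of its dollar price; \code{U_leisure}, the utility
#' of "living in denial" (neither paying nor planning); and \code{s_gain},
#' \code{s_loss}, multiplicative scalings of \code{U_outcome} for positive and
#' negative outcomes.
#'
#' @param U_outcome,C_plan,C_info,U_leisure,s_gain,s_loss numeric vectors,
#'   recycled to a common length; all strictly positive.
#' @return A data frame of class \code{voi_agents} with one row per agent.
#' @examples
#' agent_params(U_outcome = 1.5, C_plan = 0.8, C_info = 0.1, U_leisure = 0.25)
#' @export
agent_params <- function(U_outcome, C_plan, C_info, U_leisure,
                         s_gain = 1, s_loss = 1) {
  out <- data.frame(U_outcome = U_outcome, C_plan = C_plan, C_info = C_info,
                    U_leisure = U_leisure, s_gain = s_gain, s_loss = s_loss)
  validate_agents(out)
  class(out) <- c("voi_agents", "data.frame")
  out
}

validate_agents <- function(a) {
  fields <- c("U_outcome", "C_plan", "C_info", "U_leisure", "s_gain", "s_loss")
  missing <- setdiff(fields, names(a))
  if (length(missing))
    stop("agent table missing fields: ", paste(missing, collapse = ", "))
  for (f in fields) {
    x <- a[[f]]
    if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
      stop("invalid-parameter: ", f, " must be finite numeric")
    if (any(x <= 0))
      stop("invalid-parameter: ", f, " must be strictly positive")
  }
  invisible(a)
}

#' Rank-transform dollar information costs
#'
#' Maps dollar costs onto 0-based ranks within the configured cost set
#' (default \code{[$0 $5 $100] -> [0 1 2]}). Unknown cost levels are an error;
#' no interpolation is performed.
#'
#' @param cost_dollars numeric vector of dollar costs.
#' @param cost_set sorted vector of admissible cost levels.
#' @return integer vector of ranks in \code{0:(length(cost_set) - 1)}.
#' @export
rank_transform_cost <- function(cost_dollars, cost_set = c(0, 5, 100)) {
  if (anyDuplicated(cost_set)) stop("cost_set has duplicate levels")
  cost_set <- sort(cost_set)
  idx <- match(cost_dollars, cost_set)
  if (anyNA(idx))
    stop("unknown cost level(s): ",
         paste(unique(cost_dollars[is.na(idx)]), collapse = ", "))
  as.integer(idx - 1L)
}

#' Ordered cut points on the value-of-information scale
#'
#' @param kappa strictly increasing numeric vector of thresholds; 4 thresholds
#'   correspond to the study's 5 Likert categories.
#' @return numeric vector of class \code{voi_cutpoints}.
#' @export
cut_points <- function(kappa) {
  if (!is.numeric(kappa) || length(kappa) < 1 || anyNA(kappa))
    stop("invalid-cutpoints: kappa must be numeric without NAs")
  if (any(diff(kappa) <= 0))
    stop("invalid-cutpoints: kappa must be strictly increasing")
  structure(as.numeric(kappa), class = "voi_cutpoints")
}

check_scenarios <- function(sc) {
  need <- c("valence", "p", "cost_rank")
  missing <- setdiff(need, names(sc))
  if (length(missing))
    stop("scenario table missing columns: ", paste(missing, collapse = ", "))
  if (!all(sc$valence %in% c("gain", "loss")))
    stop("valence must be 'gain' or 'loss'")
  if (any(sc$p <= 0 | sc$p >= 1)) stop("p must lie strictly in (0, 1)")
  invisible(sc)
}

align_agent <- function(agent, n) {
  validate_agents(agent)
  if (nrow(agent) == 1) agent <- agent[rep(1L, n), , drop = FALSE]
  if (nrow(agent) != n)
    stop("agent rows must be 1 or match the number of scenarios")
  agent
}

#' Net utility of obtaining information
#'
#' \code{U_info = p * (s * U_outcome - C_plan) - C_info * c}, where \code{s}
#' is the valence-specific outcome scaling and \code{c} the rank-transformed
#' cost of information.
#'
#' @param agent a \code{voi_agents} row (recycled) or one row per scenario.
#' @param scenario a scenario data frame with columns \code{valence},
#'   \code{p}, \code{cost_rank} (see \code{\link{build_design_grid}}).
#' @return numeric vector of utilities, one per scenario.
#' @export
utility_info <- function(agent, scenario) {
  check_scenarios(scenario)
  a <- align_agent(agent, nrow(scenario))
  s <- ifelse(scenario$valence == "gain", a$s_gain, a$s_loss)
  scenario$p * (s * a$U_outcome - a$C_plan) - a$C_info * scenario$cost_rank
}

#' Net utility of planning in uncertainty
#'
#' \code{U_plan = p * s * U_outcome - C_plan}: the planning cost is always
#' paid, the (scaled) outcome utility is gained with probability \code{p}.
#'
#' @inheritParams utility_info
#' @return numeric vector of utilities.
#' @export
utility_plan <- function(agent, scenario) {
  check_scenarios(scenario)
  a <- align_agent(agent, nrow(scenario))
  s <- ifelse(scenario$valence == "gain", a$s_gain, a$s_loss)
  scenario$p * s * a$U_outcome - a$C_plan
}

#' Value of non-instrumental information
#'
#' \code{VOI = U_info - max(U_plan, U_leisure)}: the utility of paying for
#' information relative to the better information-free alternative (planning
#' in uncertainty, or living in denial for \code{U_leisure}). Ties at the
#' \code{U_plan = U_leisure} kink resolve toward planning.
#'
#' @inheritParams utility_info
#' @return numeric vector of utilities; piecewise linear in \code{p} with a
#'   single kink at \code{p* = (U_leisure + C_plan) / (s * U_outcome)}.
#' @examples
#' a <- agent_params(1.5, 0.8, 0.1, 0.25)
#' sc <- data.frame(valence = "gain", p = c(0.5, 0.7, 0.99), cost_rank = 1)
#' value_of_information(a, sc)
#' @export
value_of_information <- function(agent, scenario) {
  ui <- utility_info(agent, scenario)
  up <- utility_plan(agent, scenario)
  a <- align_agent(agent, nrow(scenario))
  ui - pmax(up, a$U_leisure)
}

#' Ordered-logistic response probabilities over Likert categories
#'
#' Maps a latent value of information onto the 5 ordered Likert categories
#' ("definitely not" ... "definitely yes") through cut points \code{kappa}:
#' \code{P(category <= k) = logistic(kappa_k - voi)}. Larger VOI shifts mass
#' toward "definitely yes".
#'
#' @param voi numeric vector of latent values.
#' @param kappa cut points (see \code{\link{cut_points}}).
#' @return matrix with \code{length(voi)} rows and \code{length(kappa) + 1}
#'   columns of category probabilities; rows sum to 1.
#' @export
likert_probabilities <- function(voi, kappa) {
  kappa <- cut_points(unclass(kappa))
  cum <- stats::plogis(outer(-voi, kappa, `+`))   # P(cat <= k)
  pr <- cbind(cum, 1)
  pr <- pr - cbind(0, cum)
  dimnames(pr) <- list(NULL, paste0("cat", seq_len(length(kappa) + 1)))
  pr
}

#' Display score of a Likert category
#'
#' Likert categories 1..5 ("definitely not" to "definitely yes") are scored
#' -2..+2 for visualization and cell summaries only.
#'
#' @param category integer vector in 1..5.
#' @return integer vector in -2..2.
#' @export
likert_display_score <- function(category) {
  if (any(!category %in% 1:5)) stop("category must be in 1..5")
  as.integer(category) - 3L
}

#' Likert category labels
#' @return character vector of the 5 response labels in order.
#' @export
likert_labels <- function() {
  c("definitely not", "probably not", "no preference",
    "probably yes", "definitely yes")
}
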