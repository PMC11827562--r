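#' Planted associations between agent parameters and anxiety factors
#'
#' Defines the linear map from z-scored true subject parameters (plus the
#' log outcome-scaling ratio \code{log(s_gain / s_loss)}) to the means of the
#' four trait-anxiety factor scores. The default coefficients are signs-only
#' with magnitude 0.4 SD per unit z — large enough for power at a few hundred
#' subjects — and reproduce the reported effect pattern: somatic anxiety loads
#' negatively on \code{U_outcome}, \code{C_plan}, \code{C_info} and positively
#' on \code{U_leisure}; negative affect loads negatively on \code{C_plan} and
#' positively on \code{C_info}.
#'
#' @param coefficients 7 x 4 numeric matrix (rows: the six parameters then
#'   \code{log_scale_ratio}; columns: the four factors) or NULL for defaults.
#' @param residual_sd per-factor residual SD (recycled to length 4).
#' @param magnitude effect magnitude used for the default sign pattern.
#' @return list of class \code{voi_planted}.
#' @export
planted_association <- function(coefficients = NULL, residual_sd = 1,
                                magnitude = 0.4) {
  preds <- c("U_outcome", "C_plan", "C_info", "U_leisure",
             "s_gain", "s_loss", "log_scale_ratio")
  if (is.null(coefficients)) {
    coefficients <- matrix(0, length(preds), 4,
                           dimnames = list(preds, factor_names()))
    coefficients[c("U_outcome", "C_plan", "C_info"), "somatic"] <- -magnitude
    coefficients["U_leisure", "somatic"] <- magnitude
    coefficients["C_plan", "negative_affect"] <- -magnitude
    coefficients["C_info", "negative_affect"] <- magnitude
  }
  coefficients <- as.matrix(coefficients)
  if (!identical(dim(coefficients), c(7L, 4L)))
    stop("coefficients must be a 7 x 4 matrix")
  if (any(!is.finite(coefficients))) stop("coefficients must be finite")
  rownames(coefficients) <- preds
  colnames(coefficients) <- factor_names()
  residual_sd <- rep_len(residual_sd, 4)
  if (any(residual_sd <= 0)) stop("residual SD must be > 0")
  structure(list(coefficients = coefficients, residual_sd = residual_sd),
              class = "voi_planted")
}

#' Canonical factor names
#' @return the four trait-anxiety factor names in canonical order.
#' @export
factor_names <- function() {
  c("somatic", "cognitive", "negative_affect", "low_self_esteem")
}

zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Simulate factor scores with planted parameter associations
#'
#' Each factor score is the planted linear combination of the z-scored true
#' agent parameters plus Gaussian noise, so the downstream association stage
#' has a known ground truth.
#'
#' @param agents \code{voi_agents} with a \code{subject} column (added if
#'   absent).
#' @param planted a \code{\link{planted_association}}.
#' @param seed integer seed.
#' @return data frame with \code{subject} and the four factor columns.
#' @export
simulate_factor_scores <- function(agents, planted = planted_association(),
                                   seed = 1L) {
  validate_agents(agents)
  stopifnot(inherits(planted, "voi_planted"))
  if (is.null(agents$subject)) agents$subject <- seq_len(nrow(agents))
  n <- nrow(agents)
  Z <- cbind(U_outcome = zscore(agents$U_outcome),
             C_plan = zscore(agents$C_plan),
             C_info = zscore(agents$C_info),
             U_leisure = zscore(agents$U_leisure),
             s_gain = zscore(agents$s_gain),
             s_loss = zscore(agents$s_loss),
             log_scale_ratio = zscore(log(agents$s_gain / agents$s_loss)))
  set.seed(seed)
  mu <- Z %*% planted$coefficients
  noise <- matrix(stats::rnorm(n * 4), n, 4) %*% diag(planted$residual_sd)
  scores <- as.data.frame(mu + noise)
  names(scores) <- factor_names()
  cbind(subject = agents$subject, scores)
}

#' STAIT items that are reverse coded
#'
#' The anxiety-absent STAIT items; raw responses on these are recorded in the
#' anxiety-absent orientation and must be reverse coded (\code{5 - x}) before
#' scoring. STICSAT has no reverse-coded items.
#' @return integer vector of STAIT item indices.
#' @export
stait_reverse_items <- function() c(1L, 3L, 6L, 7L, 10L, 13L, 14L, 16L, 19L)

#' Synthetic default loading configuration (41 items, 4 oblique factors)
#'
#' The numeric loading structure of the published factor solution is not
#' reproduced here; this is a synthetic stand-in with a simple-structure
#' layout so the scoring pipeline is runnable and testable end to end:
#' STICSAT items 1-11 load on somatic anxiety, STICSAT 12-21 on cognitive
#' anxiety, the reverse-coded (anxiety-absent) STAIT items on negative
#' affect, and the remaining STAIT items on low self-esteem. Primary loadings
#' are \code{loading}; uniquenesses are \code{1 - loading^2}. Supply a real
#' loading file to \code{\link{bartlett_scores}} when available.
#'
#' @param loading primary loading value (default 0.7).
#' @return list of class \code{voi_loadings} with \code{lambda} (41 x 4),
#'   \code{psi} (length-41 uniquenesses) and \code{items} metadata.
#' @export
default_loading_config <- function(loading = 0.7) {
  items <- data.frame(
    inventory = c(rep("STAIT", 20), rep("STICSAT", 21)),
    item_index = c(1:20, 1:21))
  items$reverse_coded <- items$inventory == "STAIT" &
    items$item_index %in% stait_reverse_items()
  lambda <- matrix(0, 41, 4, dimnames = list(NULL, factor_names()))
  sticsat <- which(items$inventory == "STICSAT")
  lambda[sticsat[1:11], "somatic"] <- loading
  lambda[sticsat[12:21], "cognitive"] <- loading
  lambda[which(items$reverse_coded), "negative_affect"] <- loading
  lambda[which(items$inventory == "STAIT" & !items$reverse_coded),
         "low_self_esteem"] <- loading
  loading_config(lambda, 1 - rowSums(lambda^2), items)
}

#' Assemble a loading configuration
#'
#' @param lambda 41 x 4 loading matrix with factor columns in canonical order.
#' @param psi length-41 positive uniquenesses.
#' @param items optional item metadata (inventory, item_index, reverse_coded).
#' @return list of class \code{voi_loadings}.
#' @export
loading_config <- function(lambda, psi, items = NULL) {
  lambda <- as.matrix(lambda)
  if (!identical(dim(lambda), c(41L, 4L)))
    stop("lambda must be a 41 x 4 matrix")
  if (length(psi) != 41 || any(psi <= 0))
    stop("psi must be 41 positive uniquenesses")
  colnames(lambda) <- factor_names()
  if (is.null(items)) items <- default_loading_config()$items
  structure(list(lambda = lambda, psi = as.numeric(psi), items = items),
            class = "voi_loadings")
}

#' Simulate STAIT/STICSAT questionnaire responses
#'
#' Generates continuous latent items \code{lambda f + noise} from given
#' factor scores, then discretizes each item into 4 ordered response levels
#' at fixed thresholds (default: equal-probability quartile cuts of the
#' latent item's marginal). Reverse-coded STAIT items are emitted in the
#' anxiety-absent orientation (\code{5 - coded}), so the scorer must reverse
#' them.
#'
#' @param factor_scores data frame from \code{\link{simulate_factor_scores}}
#'   (or any table with \code{subject} plus the four factor columns).
#' @param loadings a \code{voi_loadings}.
#' @param seed integer seed.
#' @param thresholds optional 41 x 3 matrix of cut thresholds on the latent
#'   item scale.
#' @return long data frame: \code{subject}, \code{inventory},
#'   \code{item_index}, \code{response} (recorded level 1..4).
#' @export
simulate_questionnaires <- function(factor_scores,
                                    loadings = default_loading_config(),
                                    seed = 1L, thresholds = NULL) {
  stopifnot(inherits(loadings, "voi_loadings"))
  f <- as.matrix(factor_scores[factor_names()])
  n <- nrow(f)
  set.seed(seed)
  latent <- f %*% t(loadings$lambda) +
    matrix(stats::rnorm(n * 41), n, 41) %*% diag(sqrt(loadings$psi))
  if (is.null(thresholds)) {
    item_sd <- sqrt(rowSums(loadings$lambda^2) + loadings$psi)
    thresholds <- t(vapply(item_sd,
                           function(s) stats::qnorm(c(0.25, 0.5, 0.75), 0, s),
                           numeric(3)))
  }
  thresholds <- as.matrix(thresholds)
  if (!identical(dim(thresholds), c(41L, 3L)))
    stop("thresholds must be 41 x 3")
  coded <- matrix(1L, n, 41)
  for (k in 1:3) coded <- coded + (latent > matrix(thresholds[, k], n, 41,
                                                   byrow = TRUE))
  recorded <- coded
  rev_cols <- which(loadings$items$reverse_coded)
  recorded[, rev_cols] <- 5L - coded[, rev_cols]
  data.frame(subject = rep(factor_scores$subject, times = 41),
             inventory = rep(loadings$items$inventory, each = n),
             item_index = rep(loadings$items$item_index, each = n),
             response = as.integer(recorded))
}
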