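#' Response label sets for the two inventories
#'
#' STAIT responses run "almost never" ... "almost always"; STICSAT responses
#' run "not at all" ... "very much so". Recorded level 1 always corresponds to
#' the first label.
#' @return named list of character vectors.
#' @export
inventory_labels <- function() {
  list(STAIT = c("almost never", "sometimes", "often", "almost always"),
       STICSAT = c("not at all", "a little", "moderately", "very much so"))
}

#' Code raw questionnaire responses into the 41-item matrix
#'
#' Items are coded 1 (no anxiety) to 4 (high anxiety). Anxiety-present items
#' map ascending with the recorded level; the reverse-coded (anxiety-absent)
#' STAIT items map \code{5 - x}, so "almost always" on those scores 1.
#' Output columns are ordered STAIT 1-20 then STICSAT 1-21.
#'
#' @param raw long data frame with columns \code{subject}, \code{inventory}
#'   ("STAIT"/"STICSAT"), \code{item_index}, and either \code{response}
#'   (recorded level 1..4) or \code{response_label}.
#' @return integer matrix (subjects x 41) with subject ids as row names.
#' @export
code_items <- function(raw) {
  need <- c("subject", "inventory", "item_index")
  if (length(setdiff(need, names(raw))))
    stop("raw responses need columns: ", paste(need, collapse = ", "))
  if (is.null(raw[["response"]])) {
    if (is.null(raw[["response_label"]]))
      stop("need a response or response_label column")
    labs <- inventory_labels()
    resp <- rep(NA_integer_, nrow(raw))
    for (inv in names(labs)) {
      i <- raw$inventory == inv
      resp[i] <- match(raw[["response_label"]][i], labs[[inv]])
    }
    raw$response <- resp
  }
  bad_inv <- !raw$inventory %in% c("STAIT", "STICSAT")
  if (any(bad_inv))
    stop("unknown inventory: ", paste(unique(raw$inventory[bad_inv]),
                                      collapse = ", "))
  n_items <- c(STAIT = 20L, STICSAT = 21L)
  bad_item <- raw$item_index < 1 | raw$item_index > n_items[raw$inventory]
  if (any(bad_item)) stop("item_index out of range for its inventory")

  subjects <- unique(raw$subject)
  col <- ifelse(raw$inventory == "STAIT", raw$item_index,
                20L + raw$item_index)
  row <- match(raw$subject, subjects)
  m <- matrix(NA_integer_, length(subjects), 41,
              dimnames = list(subjects,
                              c(paste0("STAIT_", 1:20),
                                paste0("STICSAT_", 1:21))))
  m[cbind(row, col)] <- as.integer(raw$response)

  bad <- is.na(m) | m < 1L | m > 4L
  if (any(bad)) {
    idx <- which(rowSums(bad) > 0)
    items <- apply(bad[idx, , drop = FALSE], 1,
                   function(r) paste(colnames(m)[r], collapse = ","))
    stop("missing or out-of-range responses: ",
         paste(sprintf("subject %s [%s]", rownames(m)[idx], items),
               collapse = "; "))
  }
  rev_cols <- stait_reverse_items()
  m[, rev_cols] <- 5L - m[, rev_cols]
  m
}

#' Bartlett factor scores
#'
#' Classical weighted-least-squares factor scoring: items are standardized
#' column-wise against the analysis sample, then projected through
#' \code{(lambda' psi^-1 lambda)^-1 lambda' psi^-1}. Bartlett scores are
#' conditionally unbiased under the factor model.
#'
#' @param coded subjects x 41 coded item matrix from \code{\link{code_items}}.
#' @param cfg a \code{\link{loading_config}}.
#' @return data frame of class \code{FactorScores}: \code{subject} plus the
#'   four factor columns on the z scale.
#' @export
bartlett_scores <- function(coded, cfg = default_loading_config()) {
  stopifnot(inherits(cfg, "voi_loadings"))
  coded <- as.matrix(coded)
  if (ncol(coded) != 41) stop("coded item matrix must have 41 columns")
  z <- scale(coded)
  z[is.nan(z)] <- 0      # zero-variance item carries no information
  lam <- cfg$lambda
  w <- lam / cfg$psi     # psi^-1 lambda
  gram <- crossprod(lam, w)
  if (rcond(gram) < 1e-12)
    stop("singular loading matrix: lambda is rank deficient")
  scores <- z %*% w %*% solve(gram)
  out <- as.data.frame(scores)
  names(out) <- factor_names()
  subj <- rownames(coded)
  if (is.null(subj)) subj <- as.character(seq_len(nrow(coded)))
  cbind(subject = utils::type.convert(subj, as.is = TRUE), out)
}

#' Correlations among factor scores
#'
#' @param scores a FactorScores data frame (or any table with the four
#'   factor columns).
#' @return symmetric 4 x 4 Pearson correlation matrix.
#' @export
factor_correlations <- function(scores) {
  m <- as.matrix(scores[factor_names()])
  if (nrow(m) < 3) stop("need at least 3 subjects")
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance factor: ", paste(colnames(m)[sds == 0], collapse = ", "))
  stats::cor(m)
}
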