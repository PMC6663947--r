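#' @keywords internal
"_PACKAGE"

# Probability floor applied before logs / divisions.
.P_EPS <- 1e-12

.clip_prob <- function(p) pmin(pmax(p, .P_EPS), 1 - .P_EPS)

#' Cumulative category probability (trace line)
#'
#' Probability of responding in category `j` *or higher*,
#' `P*_j(theta) = 1 / (1 + exp(-a (theta - b_j)))`. At `theta = b_j` this is
#' exactly 0.5, whatever the slope.
#'
#' @param item A [grm_item()].
#' @param j Category index in `1 .. C-1` (boundary; category 0 has `P* = 1`).
#' @param theta Numeric vector of latent-trait values.
#' @return Probabilities in `[0, 1]`, same length as `theta`.
#' @export
cumulative_prob <- function(item, j, theta) {
  stopifnot(inherits(item, "grm_item"))
  j <- as.integer(j)
  if (length(j) != 1L || j < 1L || j > length(item$b))
    stop(sprintf("category boundary j must be in 1..%d", length(item$b)), call. = FALSE)
  stats::plogis(item$a * (theta - item$b[j]))
}

# All C-1 boundary trace lines at once: |theta| x (C-1) matrix.
.cum_matrix <- function(a, b, theta) {
  stats::plogis(outer(theta, b, function(th, bb) a * (th - bb)))
}

#' Category response probabilities
#'
#' Each category probability is the difference between adjacent trace lines,
#' with the conventions `P*_0 = 1` and `P*_C = 0`; rows sum to 1.
#'
#' @inheritParams cumulative_prob
#' @return If `theta` is scalar, a probability vector of length `C`;
#'   otherwise a `|theta| x C` matrix.
#' @export
category_prob <- function(item, theta) {
  stopifnot(inherits(item, "grm_item"))
  P <- .cat_matrix(item$a, item$b, theta)
  if (length(theta) == 1L) drop(P) else P
}

# |theta| x C matrix of category probabilities.
.cat_matrix <- function(a, b, theta) {
  cum <- cbind(1, .cum_matrix(a, b, theta), 0)
  cum[, seq_len(length(b) + 1L), drop = FALSE] -
    cum[, seq_len(length(b) + 1L) + 1L, drop = FALSE]
}

#' Item characteristic curves over a grid
#'
#' @param item A [grm_item()].
#' @param grid A [theta_grid()].
#' @return `|grid| x C` matrix of category probabilities; row `t` is
#'   [category_prob()] at grid point `t`.
#' @export
icc_curve <- function(item, grid) {
  stopifnot(inherits(grid, "theta_grid"))
  .cat_matrix(item$a, item$b, grid$points)
}

#' Fisher information of one item
#'
#' Samejima's closed form for the graded response model:
#' `I(theta) = sum_k (P*'_k - P*'_{k+1})^2 / P_k`, where
#' `P*'_k = a P*_k (1 - P*_k)` and `P*_0 = 1`, `P*_C = 0`.
#'
#' @inheritParams cumulative_prob
#' @return Nonnegative information values, same length as `theta`.
#' @export
item_information <- function(item, theta) {
  stopifnot(inherits(item, "grm_item"))
  cum <- .cum_matrix(item$a, item$b, theta)            # |theta| x (C-1)
  d <- cbind(0, item$a * cum * (1 - cum), 0)           # P*' with boundaries
  C <- length(item$b) + 1L
  P <- .clip_prob(.cat_matrix(item$a, item$b, theta))
  num <- (d[, seq_len(C), drop = FALSE] - d[, seq_len(C) + 1L, drop = FALSE])^2
  rowSums(num / P)
}

#' Test information and the standard error of theta
#'
#' Information is additive over the items of a bank; the standard error of
#' the latent-trait estimate is its reciprocal square root.
#'
#' @param bank A [grm_bank()].
#' @param theta Numeric vector of latent-trait values.
#' @return Data frame with columns `theta`, `information`, `se_theta`.
#' @export
test_information <- function(bank, theta) {
  stopifnot(inherits(bank, "grm_bank"))
  if (length(bank$items) == 0L) stop("empty bank", call. = FALSE)
  info <- Reduce(`+`, lapply(bank$items, item_information, theta = theta))
  data.frame(theta = theta, information = info, se_theta = 1 / sqrt(info))
}

#' Reliability implied by an information level
#'
#' `rel = 1 - 1/I`, floored at 0: information 10 corresponds to reliability
#' 0.90, the conventional adequacy bar for short forms.
#'
#' @param information Positive information value(s).
#' @return Reliability in `[0, 1)`.
#' @export
reliability_from_information <- function(information) {
  if (any(!is.finite(information) | information <= 0))
    stop("information must be positive", call. = FALSE)
  pmax(0, 1 - 1 / information)
}

#' Expected total summed score (test characteristic curve)
#'
#' `TCC(theta) = sum_items sum_k k P_k(theta)`; monotone nondecreasing in
#' `theta`, ranging from 0 to `m (C - 1)`.
#'
#' @inheritParams test_information
#' @return Numeric vector, same length as `theta`.
#' @export
expected_total_score <- function(bank, theta) {
  stopifnot(inherits(bank, "grm_bank"))
  if (length(bank$items) == 0L) stop("empty bank", call. = FALSE)
  per_item <- lapply(bank$items, function(it) {
    P <- .cat_matrix(it$a, it$b, theta)
    drop(P %*% (seq_len(length(it$b) + 1L) - 1))
  })
  Reduce(`+`, per_item)
}

#' Expected a-posteriori scoring of respondents
#'
#' Scores each respondent on the latent trait by EAP under the population
#' prior encoded in the grid weights (standard normal by default). Missing
#' responses are simply skipped in the likelihood; a respondent with no
#' observed responses gets the prior mean and SD back, flagged.
#'
#' @param bank A [grm_bank()] whose categories match the responses.
#' @param responses A [response_matrix()].
#' @param grid A [theta_grid()]; default [normal_grid()].
#' @return Data frame with `respondent_id`, `theta`, `se`, `all_missing`.
#' @export
score_respondents <- function(bank, responses, grid = normal_grid()) {
  stopifnot(inherits(bank, "grm_bank"), inherits(responses, "response_matrix"))
  if (!all(responses$item_ids %in% names(bank$items)))
    stop("responses contain items not present in the bank", call. = FALSE)
  items <- bank$items[responses$item_ids]
  W <- .posterior_weights(items, responses$values, grid)
  theta_hat <- drop(W %*% grid$points)
  second <- drop(W %*% (grid$points^2))
  se <- sqrt(pmax(second - theta_hat^2, 0))
  all_missing <- rowSums(!is.na(responses$values)) == 0L
  # prior moments for the empty rows (already implied, but make them exact)
  mu0 <- sum(grid$weights * grid$points)
  sd0 <- sqrt(sum(grid$weights * grid$points^2) - mu0^2)
  theta_hat[all_missing] <- mu0
  se[all_missing] <- sd0
  data.frame(respondent_id = responses$respondent_ids,
             theta = theta_hat, se = se, all_missing = all_missing)
}

# Posterior weights over grid nodes, n x T; rows sum to 1.
# `prior` may be a T-vector or an n x T matrix of per-respondent priors.
.posterior_weights <- function(items, values, grid, prior = NULL) {
  logL <- .loglik_matrix(items, values, grid$points)
  if (is.null(prior)) prior <- grid$weights
  logpost <- if (is.matrix(prior)) logL + log(prior) else
    sweep(logL, 2L, log(prior), `+`)
  M <- apply(logpost, 1L, max)
  W <- exp(logpost - M)
  W / rowSums(W)
}

# n x T matrix of log-likelihoods log P(x_i | theta_t); NA responses skipped.
.loglik_matrix <- function(items, values, points) {
  n <- nrow(values); Tn <- length(points)
  logL <- matrix(0, n, Tn)
  for (j in seq_along(items)) {
    x <- values[, j]
    obs <- which(!is.na(x))
    if (!length(obs)) next
    lP <- log(.clip_prob(.cat_matrix(items[[j]]$a, items[[j]]$b, points)))  # T x C
    logL[obs, ] <- logL[obs, ] + t(lP[, x[obs] + 1L, drop = FALSE])
  }
  logL
}
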