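# Seed discipline: every stochastic operation runs inside an isolated RNG
# substream derived from (seed, tag), so injections touch only the targeted
# columns and reruns are bit-identical. Derived seeds stay below 2^31.
.substream_seed <- function(seed, tag) {
  s <- (as.double(seed) %% 2147483647) + 1
  for (k in utf8ToInt(paste0("s", tag)))
    s <- (s * 69069 + k) %% 2147483647
  as.integer(s)
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Draw latent-trait values from a normal population
#'
#' @param n Number of respondents.
#' @param mean,sd Population mean and SD (default standard normal, the
#'   metric the item parameters are identified on).
#' @param seed Integer seed; required, every draw is reproducible.
#' @return Numeric vector of length `n`.
#' @export
sample_theta <- function(n, mean = 0, sd = 1, seed) {
  stopifnot(n >= 1, sd > 0, !missing(seed))
  .with_seed(.substream_seed(seed, "theta"), stats::rnorm(n, mean, sd))
}

#' Local-dependence injection hook
#'
#' Marks a pair of items whose responses are generated from a shared
#' testlet-style nuisance factor: both items see
#' `theta' = (theta + strength * u) / sqrt(1 + strength^2)` with `u ~ N(0,1)`
#' shared within respondent, so the marginal trait variance stays 1 and
#' `strength = 0` recovers independent generation. This creates the excess
#' pairwise covariance, beyond the common trait, that the LD statistic
#' targets.
#'
#' @param bank Bank the items must belong to (validation only).
#' @param item_pair Character vector of two distinct item ids.
#' @param strength Nuisance loading in `[0, 1)`.
#' @return A hook object for [simulate_responses()].
#' @export
inject_local_dependence <- function(bank, item_pair, strength) {
  stopifnot(inherits(bank, "grm_bank"))
  item_pair <- as.character(item_pair)
  if (length(item_pair) != 2L || item_pair[1] == item_pair[2])
    stop("item_pair must name two distinct items", call. = FALSE)
  if (!all(item_pair %in% names(bank$items)))
    stop("item_pair not found in bank", call. = FALSE)
  if (!is.numeric(strength) || strength < 0 || strength >= 1)
    stop("strength must lie in [0, 1)", call. = FALSE)
  structure(list(type = "ld", items = item_pair, strength = strength),
            class = "sim_hook")
}

#' Item-misfit injection hook
#'
#' Two mechanisms: `"second_dimension"` generates the item from the mixed
#' trait `0.5 theta + 0.866 eta` (`eta` independent standard normal), so the
#' item only weakly tracks the trait the rest of the scale measures;
#' `"category_scramble"` swaps the lowest and middle category labels of the
#' generated responses, breaking the graded (monotone) category structure.
#'
#' @param bank Bank the item must belong to (validation only).
#' @param item_id Item to corrupt.
#' @param mechanism `"second_dimension"` or `"category_scramble"`.
#' @return A hook object for [simulate_responses()].
#' @export
inject_misfit <- function(bank, item_id, mechanism = c("second_dimension", "category_scramble")) {
  stopifnot(inherits(bank, "grm_bank"))
  mechanism <- match.arg(mechanism)
  item_id <- as.character(item_id)
  if (!item_id %in% names(bank$items)) stop("item not found in bank", call. = FALSE)
  structure(list(type = "misfit", items = item_id, mechanism = mechanism),
            class = "sim_hook")
}

#' Simulate graded responses from a bank
#'
#' Each response is drawn from the item's category distribution at the
#' respondent's latent-trait value; missingness is injected completely at
#' random at rate `missing_rate`. Each item consumes its own RNG substream,
#' so injection hooks alter only the targeted columns (bit-for-bit) and the
#' same `(bank, theta, seed)` always reproduces the same matrix.
#'
#' @param bank A [grm_bank()].
#' @param theta Numeric vector of latent-trait values (one per respondent).
#' @param missing_rate MCAR missingness probability in `[0, 0.5]`.
#' @param seed Integer seed (required).
#' @param hooks Optional list of [inject_local_dependence()] /
#'   [inject_misfit()] hooks.
#' @return A [response_matrix()].
#' @export
simulate_responses <- function(bank, theta, missing_rate = 0, seed, hooks = list()) {
  stopifnot(inherits(bank, "grm_bank"), !missing(seed))
  if (missing_rate < 0 || missing_rate > 0.5)
    stop("missing_rate must lie in [0, 0.5]", call. = FALSE)
  if (inherits(hooks, "sim_hook")) hooks <- list(hooks)
  n <- length(theta)
  m <- length(bank$items)
  ids <- names(bank$items)
  C_all <- vapply(bank$items, ncat, integer(1))

  ld_theta <- list()  # per-item override of the generating trait
  scramble <- character(0)
  second_dim <- character(0)
  for (h in seq_along(hooks)) {
    hk <- hooks[[h]]
    if (!inherits(hk, "sim_hook")) stop("hooks must be sim_hook objects", call. = FALSE)
    if (hk$type == "ld") {
      u <- .with_seed(.substream_seed(seed, paste0("ld", h)), stats::rnorm(n))
      th <- (theta + hk$strength * u) / sqrt(1 + hk$strength^2)
      for (id in hk$items) ld_theta[[id]] <- th
    } else if (hk$mechanism == "second_dimension") {
      second_dim <- c(second_dim, hk$items)
    } else {
      scramble <- c(scramble, hk$items)
    }
  }

  vals <- matrix(NA_integer_, n, m, dimnames = list(NULL, ids))
  for (j in seq_len(m)) {
    id <- ids[j]
    it <- bank$items[[j]]
    vals[, j] <- .with_seed(.substream_seed(seed, paste0("item", j)), {
      th <- if (!is.null(ld_theta[[id]])) ld_theta[[id]] else theta
      if (id %in% second_dim)
        th <- 0.5 * th + 0.866 * stats::rnorm(n)
      u <- stats::runif(n)
      cum <- .cum_matrix(it$a, it$b, th)        # n x (C-1), decreasing in k
      x <- as.integer(rowSums(u < cum))
      if (id %in% scramble) {
        mid <- (ncat(it) - 1L) %/% 2L
        lo <- x == 0L
        x[x == mid] <- 0L
        x[lo] <- mid
      }
      if (missing_rate > 0)
        x[stats::runif(n) < missing_rate] <- NA_integer_
      x
    })
  }
  response_matrix(vals, C = max(C_all), item_ids = ids)
}

#' Uniform / non-uniform DIF injection
#'
#' Returns the focal-group bank: the targeted item's thresholds are shifted
#' by `b_shift` (a negative shift makes the focal group endorse every
#' category at lower trait levels — uniform DIF) and its slope is multiplied
#' by `a_ratio` (non-uniform DIF when different from 1). All other items are
#' untouched.
#'
#' @param bank Reference-group [grm_bank()].
#' @param item_id Item receiving DIF.
#' @param b_shift Additive threshold shift (preserves threshold order).
#' @param a_ratio Positive multiplicative slope change.
#' @return The focal-group [grm_bank()].
#' @export
inject_dif <- function(bank, item_id, b_shift = 0, a_ratio = 1) {
  stopifnot(inherits(bank, "grm_bank"))
  if (!item_id %in% names(bank$items)) stop("item not found in bank", call. = FALSE)
  if (!is.numeric(a_ratio) || a_ratio <= 0) stop("a_ratio must be positive", call. = FALSE)
  focal <- bank
  it <- focal$items[[item_id]]
  focal$items[[item_id]] <- grm_item(it$item_id, it$a * a_ratio, it$b + b_shift)
  focal
}

#' Simulate a full two-group study
#'
#' Convenience generator emulating the field-study conditions the package's
#' diagnostics were designed around: by default 825 respondents, a 49/51
#' reference/focal gender split, latent trait standard normal in both groups,
#' and 5.5% item-level missingness, using the packaged 51-item bank. Any
#' piece can be overridden, and a focal-specific bank (e.g. from
#' [inject_dif()]) induces true DIF.
#'
#' @param n Total respondents (default 825).
#' @param bank Reference bank (default the packaged 51-item fixture bank).
#' @param focal_bank Bank generating focal-group responses (default: same).
#' @param focal_fraction Share of focal-group respondents (default 0.51).
#' @param theta_mean,theta_sd Population moments, length-2 `(reference,
#'   focal)` or scalars.
#' @param missing_rate MCAR missingness (default 0.055).
#' @param seed Integer seed (required).
#' @param hooks Injection hooks passed to [simulate_responses()].
#' @return List with `responses` ([response_matrix()]), `groups` (factor
#'   `reference`/`focal`), and `theta`.
#' @export
simulate_study <- function(n = 825, bank = NULL, focal_bank = NULL,
                           focal_fraction = 0.51,
                           theta_mean = c(0, 0), theta_sd = c(1, 1),
                           missing_rate = 0.055, seed, hooks = list()) {
  stopifnot(!missing(seed))
  if (is.null(bank)) bank <- depression_fixture()$bank
  if (is.null(focal_bank)) focal_bank <- bank
  theta_mean <- rep(theta_mean, length.out = 2L)
  theta_sd <- rep(theta_sd, length.out = 2L)
  n_focal <- round(n * focal_fraction)
  n_ref <- n - n_focal
  th_ref <- sample_theta(n_ref, theta_mean[1], theta_sd[1], seed = .substream_seed(seed, "ref"))
  th_foc <- sample_theta(n_focal, theta_mean[2], theta_sd[2], seed = .substream_seed(seed, "foc"))
  resp_ref <- simulate_responses(bank, th_ref, missing_rate,
                                 seed = .substream_seed(seed, "rref"), hooks = hooks)
  resp_foc <- simulate_responses(focal_bank, th_foc, missing_rate,
                                 seed = .substream_seed(seed, "rfoc"), hooks = hooks)
  vals <- rbind(resp_ref$values, resp_foc$values)
  responses <- response_matrix(vals, C = max(resp_ref$C, resp_foc$C),
                               item_ids = resp_ref$item_ids)
  list(responses = responses,
       groups = factor(rep(c("reference", "focal"), c(n_ref, n_focal)),
                       levels = c("reference", "focal")),
       theta = c(th_ref, th_foc))
}
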