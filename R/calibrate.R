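#' Calibration settings
#'
#' @param grid_points Number of quadrature nodes (default 121). The node
#'   spacing must stay below each respondent's posterior SD
#'   (about `1/sqrt(test information)`), or the discretized likelihood
#'   develops spurious ripples that bias the thresholds.
#' @param grid_range Latent-trait range covered by the grid (default
#'   `c(-6, 6)`); widen for items with extreme thresholds.
#' @param tol EM convergence tolerance: maximum absolute parameter change,
#'   on the natural `(a, b)` scale (default 1e-4).
#' @param max_cycles Maximum EM cycles (default 500).
#' @param on_unobserved What to do when an item has a response category
#'   nobody used: `"error"` (default) or `"collapse"` (merge the empty
#'   category into its lower neighbour and fit the item with fewer
#'   categories).
#' @param se Compute observed-information (OPG) standard errors after
#'   convergence (default `TRUE`).
#' @param prior Optional MAP prior, a list with elements
#'   `a = c(meanlog, sdlog)` (lognormal on the slope) and `b = c(mean, sd)`
#'   (normal on each threshold). `NULL` (default) = plain maximum
#'   likelihood.
#' @param prior_mean,prior_sd Moments of the (fixed) normal population the
#'   latent trait is integrated over. The defaults (0, 1) identify the
#'   metric; group-specific values are used by the DIF workflow.
#' @return A list of class `grm_control`.
#' @export
grm_control <- function(grid_points = 121L, grid_range = c(-6, 6),
                        tol = 1e-4, max_cycles = 500L,
                        on_unobserved = c("error", "collapse"),
                        se = TRUE, prior = NULL,
                        prior_mean = 0, prior_sd = 1) {
  on_unobserved <- match.arg(on_unobserved)
  stopifnot(grid_points >= 5L, length(grid_range) == 2L, tol > 0, max_cycles >= 1L,
            prior_sd > 0)
  structure(list(grid_points = as.integer(grid_points),
                 grid_range = as.numeric(grid_range),
                 tol = tol, max_cycles = as.integer(max_cycles),
                 on_unobserved = on_unobserved, se = se, prior = prior,
                 prior_mean = prior_mean, prior_sd = prior_sd),
            class = "grm_control")
}

# ---- parameter transforms -------------------------------------------------
# Free parameterization: phi = (log a, b_1, log(b_2 - b_1), ...) keeps the
# slope positive and the thresholds strictly ordered.
.phi_from_ab <- function(a, b) {
  if (length(b) == 1L) c(log(a), b) else c(log(a), b[1], log(diff(b)))
}
.ab_from_phi <- function(phi) {
  a <- exp(phi[1])
  b <- if (length(phi) == 2L) phi[2] else cumsum(c(phi[2], exp(phi[-(1:2)])))
  list(a = a, b = b)
}

# ---- M-step objective -----------------------------------------------------
# Negative expected complete-data log-likelihood for one item given the
# T x C table of expected counts R, plus analytic gradient in phi.
.mstep_obj <- function(phi, R, points, prior = NULL) {
  p <- .ab_from_phi(phi)
  P <- .clip_prob(.cat_matrix(p$a, p$b, points))
  val <- -sum(R * log(P))
  if (!is.null(prior)) {
    val <- val - stats::dnorm(phi[1], prior$a[1], prior$a[2], log = TRUE) -
      sum(stats::dnorm(p$b, prior$b[1], prior$b[2], log = TRUE))
  }
  val
}

.mstep_grad <- function(phi, R, points, prior = NULL) {
  p <- .ab_from_phi(phi)
  a <- p$a; b <- p$b
  C <- length(b) + 1L
  cum <- .cum_matrix(a, b, points)                  # T x (C-1)
  s <- cum * (1 - cum)
  P <- .clip_prob(.cat_matrix(a, b, points))
  RP <- R / P                                       # T x C
  # d/da: dP_k/da = u_k s_k - u_{k+1} s_{k+1}, u_k = theta - b_k (s_0=s_C=0)
  us <- s * outer(points, b, `-`)
  usb <- cbind(0, us, 0)
  dPda <- usb[, seq_len(C), drop = FALSE] - usb[, seq_len(C) + 1L, drop = FALSE]
  g_a <- -sum(RP * dPda)
  # d/db_l: dP_{l-1}/db_l = a s_l ; dP_l/db_l = -a s_l   (categories 0-based)
  g_b <- vapply(seq_len(C - 1L), function(l)
    -sum(a * s[, l] * (RP[, l] - RP[, l + 1L])), numeric(1))
  if (!is.null(prior)) {
    g_a <- g_a - (prior$a[1] - phi[1]) / prior$a[2]^2 / a  # d(-logprior)/da
    g_b <- g_b + (b - prior$b[1]) / prior$b[2]^2
  }
  # chain rule into phi
  g <- numeric(length(phi))
  g[1] <- g_a * a
  if (length(b) == 1L) {
    g[2] <- g_b
  } else {
    g[2] <- sum(g_b)
    gaps <- exp(phi[-(1:2)])
    for (k in seq_along(gaps))
      g[2L + k] <- sum(g_b[(k + 1L):length(g_b)]) * gaps[k]
  }
  g
}

# ---- category collapse ----------------------------------------------------
# Remap each item's codes to consecutive 0..C_eff-1 over observed categories.
.collapse_categories <- function(values, C, on_unobserved) {
  m <- ncol(values)
  maps <- vector("list", m)
  collapsed <- logical(m)
  for (j in seq_len(m)) {
    x <- values[, j]
    cnt <- tabulate(x + 1L, nbins = C)
    if (sum(cnt > 0L) < 2L)
      stop(sprintf("item %d has fewer than 2 observed categories", j), call. = FALSE)
    if (any(cnt == 0L)) {
      if (on_unobserved == "error")
        stop(sprintf("item '%s' has unobserved categories (%s); use on_unobserved = \"collapse\" or pool data",
                     colnames(values)[j],
                     paste(which(cnt == 0L) - 1L, collapse = ", ")),
             call. = FALSE)
      obs_cats <- which(cnt > 0L) - 1L
      map <- rep(NA_integer_, C)
      map[obs_cats + 1L] <- seq_along(obs_cats) - 1L
      values[, j] <- map[x + 1L]
      maps[[j]] <- obs_cats
      collapsed[j] <- TRUE
    } else {
      maps[[j]] <- 0:(C - 1L)
    }
  }
  list(values = values, maps = maps, collapsed = collapsed)
}

# ---- start values ---------------------------------------------------------
.start_item <- function(x, C) {
  n <- sum(!is.na(x))
  pgeq <- vapply(seq_len(C - 1L), function(k) (sum(x >= k, na.rm = TRUE) + 0.5) / (n + 1), numeric(1))
  b <- stats::qnorm(1 - pgeq)
  b <- pmin(pmax(b, -3.5), 3.5)
  # enforce strict order with a minimum gap
  for (k in seq_len(C - 1L)[-1]) b[k] <- max(b[k], b[k - 1L] + 0.05)
  list(a = 1.5, b = b)
}

#' Fit the graded response model by marginal maximum likelihood
#'
#' Bock-Aitkin EM on a fixed quadrature grid: the E-step computes each
#' respondent's posterior over the grid under the standard-normal population
#' (which also identifies the latent metric), and the M-step refits each
#' item by Newton-type maximization (BFGS with analytic gradients) of its
#' expected complete-data log-likelihood. Missing responses simply drop out
#' of the likelihood; no imputation or listwise deletion.
#'
#' @param responses A [response_matrix()].
#' @param control A [grm_control()].
#' @param start Optional starting [grm_bank()].
#' @return An object of class `grm_fit`: a list with `bank` (estimates),
#'   `se` (per-parameter standard errors, same shape as the parameter
#'   frame), `loglik`, `n_effective`, `converged`, `n_cycles`, `ll_trace`,
#'   `grid`, `collapse` (per-item retained original categories) and
#'   `control`.
#' @export
fit_grm <- function(responses, control = grm_control(), start = NULL) {
  stopifnot(inherits(responses, "response_matrix"), inherits(control, "grm_control"))
  values <- responses$values
  C <- responses$C
  m <- ncol(values)
  cl <- .collapse_categories(values, C, control$on_unobserved)
  values <- cl$values
  Ceff <- vapply(cl$maps, length, integer(1))

  grid <- normal_grid(control$grid_points, control$grid_range,
                      control$prior_mean, control$prior_sd)
  pts <- grid$points

  prior <- control$prior
  if (!is.null(prior)) {
    stopifnot(is.list(prior), length(prior$a) == 2L, length(prior$b) == 2L)
  }

  items <- vector("list", m)
  for (j in seq_len(m)) {
    st <- if (!is.null(start)) {
      it <- start$items[[responses$item_ids[j]]]
      list(a = it$a, b = it$b)
    } else .start_item(values[, j], Ceff[j])
    items[[j]] <- grm_item(responses$item_ids[j], st$a, st$b)
  }

  obs_idx <- lapply(seq_len(m), function(j) which(!is.na(values[, j])))
  ll_trace <- numeric(0)
  converged <- FALSE
  cycle <- 0L
  repeat {
    cycle <- cycle + 1L
    logL <- .loglik_matrix(items, values, pts)
    logpost <- sweep(logL, 2L, log(grid$weights), `+`)
    M <- apply(logpost, 1L, max)
    E <- exp(logpost - M)
    rs <- rowSums(E)
    ll_trace <- c(ll_trace, sum(M + log(rs)))
    W <- E / rs

    max_delta <- 0
    for (j in seq_len(m)) {
      obs <- obs_idx[[j]]
      x <- values[obs, j]
      # expected counts: R[t, k] = sum_i W_it 1{x_ij = k}
      R <- t(rowsum(W[obs, , drop = FALSE], group = x, reorder = TRUE))
      if (ncol(R) < Ceff[j]) { # categories can be absent only pre-collapse
        full <- matrix(0, length(pts), Ceff[j])
        full[, as.integer(colnames(R)) + 1L] <- R
        R <- full
      }
      it <- items[[j]]
      phi0 <- .phi_from_ab(it$a, it$b)
      opt <- stats::optim(phi0, .mstep_obj, .mstep_grad, R = R, points = pts,
                          prior = prior, method = "BFGS",
                          control = list(maxit = 60, reltol = 1e-12))
      new <- .ab_from_phi(opt$par)
      max_delta <- max(max_delta, abs(new$a - it$a), max(abs(new$b - it$b)))
      items[[j]] <- grm_item(it$item_id, new$a, new$b)
    }
    if (max_delta < control$tol) { converged <- TRUE; break }
    if (cycle >= control$max_cycles) break
  }
  if (!converged)
    warning(sprintf("EM did not converge in %d cycles (last max delta %.2e)",
                    cycle, max_delta))

  bank <- grm_bank(items)
  loglik <- loglikelihood(bank, response_matrix(values, C = max(Ceff),
                                                respondent_ids = responses$respondent_ids,
                                                item_ids = responses$item_ids),
                          grid)
  fit <- structure(list(bank = bank, se = NULL, loglik = loglik,
                        n_effective = sum(rowSums(!is.na(values)) > 0L),
                        converged = converged, n_cycles = cycle,
                        ll_trace = ll_trace, grid = grid,
                        collapse = cl$maps, collapsed = cl$collapsed,
                        values = values, item_ids = responses$item_ids,
                        respondent_ids = responses$respondent_ids,
                        C = C, control = control),
                   class = "grm_fit")
  if (control$se && converged)
    fit$se <- tryCatch(standard_errors(fit), error = function(e) {
      warning(conditionMessage(e)); NULL
    })
  fit
}

#' @export
print.grm_fit <- function(x, ...) {
  cat(sprintf("<grm_fit> %d items, n = %d, logLik = %.2f, %s in %d cycles\n",
              length(x$bank$items), x$n_effective, x$loglik,
              if (x$converged) "converged" else "NOT converged", x$n_cycles))
  invisible(x)
}

#' Marginal log-likelihood of a bank for observed responses
#'
#' `sum_i log sum_t w_t prod_j P(x_ij | theta_t)`; all-missing respondents
#' contribute zero, and an empty response set has log-likelihood 0.
#'
#' @param bank A [grm_bank()].
#' @param responses A [response_matrix()] (or plain integer matrix, possibly
#'   with zero rows).
#' @param grid A [theta_grid()].
#' @return Scalar log-likelihood.
#' @export
loglikelihood <- function(bank, responses, grid = normal_grid()) {
  stopifnot(inherits(bank, "grm_bank"))
  values <- if (inherits(responses, "response_matrix")) responses$values else as.matrix(responses)
  if (nrow(values) == 0L) return(0)
  ids <- colnames(values)
  items <- if (!is.null(ids) && all(ids %in% names(bank$items))) bank$items[ids] else bank$items
  stopifnot(length(items) == ncol(values))
  logL <- .loglik_matrix(items, values, grid$points)
  logpost <- sweep(logL, 2L, log(grid$weights), `+`)
  M <- apply(logpost, 1L, max)
  sum(M + log(rowSums(exp(logpost - M))))
}

#' Observed-information (OPG) standard errors
#'
#' Approximates the information matrix by the empirical cross-product of
#' per-respondent score vectors of the marginal likelihood (outer product of
#' gradients), evaluated at the EM solution, and returns the square roots of
#' the diagonal of its inverse. Well suited to Wald-type DIF tests at these
#' sample sizes.
#'
#' @param fit A converged [fit_grm()] result.
#' @param responses Optional [response_matrix()]; defaults to the data the
#'   model was fitted to.
#' @return Data frame with columns `item_id`, `se_a`, `se_b1`, `se_b2`, ...
#' @export
standard_errors <- function(fit, responses = NULL) {
  stopifnot(inherits(fit, "grm_fit"))
  if (!fit$converged) stop("standard errors require a converged fit", call. = FALSE)
  values <- if (is.null(responses)) fit$values else responses$values
  items <- fit$bank$items
  grid <- fit$grid
  pts <- grid$points
  n <- nrow(values)
  W <- .posterior_weights(items, values, grid)
  npar <- vapply(items, function(it) length(it$b) + 1L, integer(1))
  q <- sum(npar)
  G <- matrix(0, n, q)
  col0 <- cumsum(c(0L, npar[-length(npar)]))
  for (j in seq_along(items)) {
    it <- items[[j]]
    C <- length(it$b) + 1L
    cum <- .cum_matrix(it$a, it$b, pts)
    s <- cum * (1 - cum)
    P <- .clip_prob(.cat_matrix(it$a, it$b, pts))
    usb <- cbind(0, s * outer(pts, it$b, `-`), 0)
    dPda <- (usb[, seq_len(C), drop = FALSE] -
               usb[, seq_len(C) + 1L, drop = FALSE]) / P   # T x C, dlogP/da
    x <- values[, j]
    obs <- which(!is.na(x))
    xi <- x[obs] + 1L
    Wt <- t(W[obs, , drop = FALSE])                        # T x n_obs
    G[obs, col0[j] + 1L] <- colSums(Wt * dPda[, xi, drop = FALSE])
    for (l in seq_len(C - 1L)) {
      Dl <- matrix(0, length(pts), C)
      Dl[, l] <- it$a * s[, l] / P[, l]
      Dl[, l + 1L] <- -it$a * s[, l] / P[, l + 1L]
      G[obs, col0[j] + 1L + l] <- colSums(Wt * Dl[, xi, drop = FALSE])
    }
  }
  info <- crossprod(G)
  V <- tryCatch(solve(info), error = function(e) {
    d <- abs(diag(info))
    worst <- which.min(d)
    item_of <- rep(seq_along(items), npar)
    stop(sprintf("information matrix is singular near item '%s'",
                 items[[item_of[worst]]]$item_id), call. = FALSE)
  })
  se <- sqrt(pmax(diag(V), 0))
  nb <- max(npar) - 1L
  out <- data.frame(item_id = names(items), se_a = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_len(nb)) out[[paste0("se_b", k)]] <- NA_real_
  for (j in seq_along(items)) {
    out$se_a[j] <- se[col0[j] + 1L]
    for (l in seq_len(npar[j] - 1L))
      out[[paste0("se_b", l)]][j] <- se[col0[j] + 1L + l]
  }
  attr(out, "vcov") <- V
  attr(out, "index") <- data.frame(item = rep(names(items), npar),
                                   par = unlist(lapply(npar, function(k)
                                     c("a", paste0("b", seq_len(k - 1L))))),
                                   col = seq_len(q), stringsAsFactors = FALSE)
  out
}

#' Parameter table of a fit
#'
#' @param fit A [fit_grm()] result.
#' @return Data frame `item_id, a, b1..`, joined with `se_*` columns when
#'   standard errors are available.
#' @export
coef_table <- function(fit) {
  stopifnot(inherits(fit, "grm_fit"))
  out <- as.data.frame(fit$bank)
  if (!is.null(fit$se)) out <- merge(out, fit$se, by = "item_id", sort = FALSE)
  out
}
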