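# Per-item derivative tables: list over parameters (a, b_1..b_{C-1}) of
# T x C matrices dP_k / dpar at the grid points.
.dP_tables <- function(it, points) {
  C <- length(it$b) + 1L
  cum <- .cum_matrix(it$a, it$b, points)
  s <- cum * (1 - cum)
  usb <- cbind(0, s * outer(points, it$b, `-`), 0)
  out <- vector("list", C)
  out[[1]] <- usb[, seq_len(C), drop = FALSE] - usb[, seq_len(C) + 1L, drop = FALSE]
  for (l in seq_len(C - 1L)) {
    D <- matrix(0, length(points), C)
    D[, l] <- it$a * s[, l]
    D[, l + 1L] <- -it$a * s[, l]
    out[[l + 1L]] <- D
  }
  out
}

# Limited-information M2 fit statistic on univariate + bivariate margins
# (category 0 dropped per item to keep the margin covariance nonsingular).
# Returns list(m2, df, p) or NULL when not computable.
.m2_statistic <- function(items, values, grid, margin_cap = 6000) {
  m <- length(items)
  if (m < 2L) return(NULL)
  Cs <- vapply(items, function(it) length(it$b) + 1L, integer(1))
  s_uni <- sum(Cs - 1L)
  pair_idx <- utils::combn(m, 2L)
  s_biv <- sum((Cs[pair_idx[1, ]] - 1L) * (Cs[pair_idx[2, ]] - 1L))
  s <- s_uni + s_biv
  q <- sum(Cs)
  if (s > margin_cap) {
    warning(sprintf("M2 skipped: %d margins exceed cap %d", s, margin_cap))
    return(NULL)
  }
  if (q >= s) {
    warning("M2 undefined: at least as many parameters as margins")
    return(NULL)
  }
  n <- nrow(values)
  w <- grid$weights
  Tn <- length(grid$points)
  P <- lapply(items, function(it) .cat_matrix(it$a, it$b, grid$points))
  dP <- lapply(items, .dP_tables, points = grid$points)

  # --- event bookkeeping (uni first, then biv in pair order) ---------------
  uni_row <- function(j, k) sum(Cs[seq_len(j - 1L)] - 1L) + k
  biv_base <- integer(ncol(pair_idx))
  off <- s_uni
  for (pp in seq_len(ncol(pair_idx))) {
    biv_base[pp] <- off
    off <- off + (Cs[pair_idx[1, pp]] - 1L) * (Cs[pair_idx[2, pp]] - 1L)
  }
  pair_no <- matrix(0L, m, m)
  for (pp in seq_len(ncol(pair_idx)))
    pair_no[pair_idx[1, pp], pair_idx[2, pp]] <- pp
  # rows of pair pp as a (Cj-1) x (Cl-1) index matrix [cat_j, cat_l]
  biv_rows <- function(pp) {
    j <- pair_idx[1, pp]; l <- pair_idx[2, pp]
    matrix(biv_base[pp] + seq_len((Cs[j] - 1L) * (Cs[l] - 1L)),
           nrow = Cs[j] - 1L, byrow = FALSE)
  }

  # --- V (s x T), model margins pi, observed margins p ---------------------
  V <- matrix(0, s, Tn)
  pobs <- numeric(s)
  for (j in seq_len(m)) for (k in seq_len(Cs[j] - 1L)) {
    V[uni_row(j, k), ] <- P[[j]][, k + 1L]
    pobs[uni_row(j, k)] <- mean(values[, j] == k)
  }
  for (pp in seq_len(ncol(pair_idx))) {
    j <- pair_idx[1, pp]; l <- pair_idx[2, pp]
    rows <- biv_rows(pp)
    for (kj in seq_len(Cs[j] - 1L)) for (kl in seq_len(Cs[l] - 1L)) {
      V[rows[kj, kl], ] <- P[[j]][, kj + 1L] * P[[l]][, kl + 1L]
      pobs[rows[kj, kl]] <- mean(values[, j] == kj & values[, l] == kl)
    }
  }
  pi_mod <- drop(V %*% w)

  # --- Jacobian (s x q) ----------------------------------------------------
  par_base <- cumsum(c(0L, Cs[-m]))
  Delta <- matrix(0, s, q)
  for (j in seq_len(m)) for (pidx in seq_len(Cs[j])) {
    dcol <- dP[[j]][[pidx]]
    for (k in seq_len(Cs[j] - 1L))
      Delta[uni_row(j, k), par_base[j] + pidx] <- sum(w * dcol[, k + 1L])
  }
  for (pp in seq_len(ncol(pair_idx))) {
    j <- pair_idx[1, pp]; l <- pair_idx[2, pp]
    rows <- biv_rows(pp)
    for (kj in seq_len(Cs[j] - 1L)) for (kl in seq_len(Cs[l] - 1L)) {
      r <- rows[kj, kl]
      for (pidx in seq_len(Cs[j]))
        Delta[r, par_base[j] + pidx] <- sum(w * dP[[j]][[pidx]][, kj + 1L] * P[[l]][, kl + 1L])
      for (pidx in seq_len(Cs[l]))
        Delta[r, par_base[l] + pidx] <- sum(w * P[[j]][, kj + 1L] * dP[[l]][[pidx]][, kl + 1L])
    }
  }

  # --- Gamma = E[eta eta'] - pi pi' ---------------------------------------
  Vw <- V * rep(w, each = s)
  Gamma <- Vw %*% t(V)                       # correct for item-disjoint events
  # uni-uni, same item
  for (j in seq_len(m)) {
    rows <- vapply(seq_len(Cs[j] - 1L), function(k) uni_row(j, k), integer(1))
    Gamma[rows, rows] <- diag(pi_mod[rows], nrow = length(rows))
  }
  # uni-biv sharing the item
  for (pp in seq_len(ncol(pair_idx))) {
    j <- pair_idx[1, pp]; l <- pair_idx[2, pp]
    rows <- biv_rows(pp)
    for (k in seq_len(Cs[j] - 1L)) {
      ur <- uni_row(j, k)
      blk <- matrix(0, Cs[j] - 1L, Cs[l] - 1L)
      blk[k, ] <- pi_mod[rows[k, ]]
      Gamma[ur, as.vector(rows)] <- as.vector(blk)
      Gamma[as.vector(rows), ur] <- as.vector(blk)
    }
    for (k in seq_len(Cs[l] - 1L)) {
      ur <- uni_row(l, k)
      blk <- matrix(0, Cs[j] - 1L, Cs[l] - 1L)
      blk[, k] <- pi_mod[rows[, k]]
      Gamma[ur, as.vector(rows)] <- as.vector(blk)
      Gamma[as.vector(rows), ur] <- as.vector(blk)
    }
  }
  # biv-biv, same pair
  for (pp in seq_len(ncol(pair_idx))) {
    rows <- as.vector(biv_rows(pp))
    Gamma[rows, rows] <- diag(pi_mod[rows], nrow = length(rows))
  }
  # biv-biv sharing exactly one item
  for (p1 in seq_len(ncol(pair_idx) - 1L)) for (p2 in (p1 + 1L):ncol(pair_idx)) {
    it1 <- pair_idx[, p1]; it2 <- pair_idx[, p2]
    shared <- intersect(it1, it2)
    if (length(shared) != 1L) next
    sj <- shared
    u <- setdiff(it1, sj); v <- setdiff(it2, sj)
    r1 <- biv_rows(p1); r2 <- biv_rows(p2)
    # orient rows so dim 1 = shared-item category
    if (it1[1] != sj) r1 <- t(r1)
    if (it2[1] != sj) r2 <- t(r2)
    n1 <- ncol(r1); n2 <- ncol(r2)
    E <- matrix(0, (Cs[sj] - 1L) * n1, (Cs[sj] - 1L) * n2)
    rows1 <- as.vector(t(r1)); rows2 <- as.vector(t(r2))  # grouped by shared cat
    for (cc in seq_len(Cs[sj] - 1L)) {
      ws <- w * P[[sj]][, cc + 1L]
      Tc <- t(P[[u]][, -1L, drop = FALSE] * ws) %*% P[[v]][, -1L, drop = FALSE]
      E[(cc - 1L) * n1 + seq_len(n1), (cc - 1L) * n2 + seq_len(n2)] <- Tc
    }
    Gamma[rows1, rows2] <- E
    Gamma[rows2, rows1] <- t(E)
  }
  Gamma <- Gamma - tcrossprod(pi_mod)

  e <- pobs - pi_mod
  res <- tryCatch({
    Gi_D <- solve(Gamma, Delta)
    Gi_e <- solve(Gamma, e)
    A <- solve(crossprod(Delta, Gi_D), crossprod(Gi_D, e))
    stat <- n * (sum(e * Gi_e) - sum(crossprod(Delta, Gi_e) * A))
    stat
  }, error = function(err) {
    warning("M2 weight matrix is singular; statistic not computed")
    NULL
  })
  if (is.null(res)) return(NULL)
  df <- s - q
  list(m2 = max(res, 0), df = df,
       p = stats::pchisq(max(res, 0), df, lower.tail = FALSE))
}

#' Scale-level model fit statistics
#'
#' Bundles the marginal -2 log-likelihood with AIC / BIC (by their defining
#' identities), the limited-information M2 statistic on univariate and
#' bivariate margins with its RMSEA, Cronbach's alpha, and marginal
#' reliability. M2 uses complete cases; it is returned as `NA` (with a
#' warning) when the margin count exceeds `m2_margin_cap` — for a 51-item
#' five-category bank the full margin vector is over 20,000 entries and its
#' weight matrix is not worth materializing.
#'
#' @param fit A converged [fit_grm()].
#' @param m2 Compute M2/RMSEA (default `TRUE`).
#' @param m2_margin_cap Margin-count cap for M2 (default 6000).
#' @return A list of class `model_fit_stats`: `minus2ll`, `n_params`, `aic`,
#'   `bic`, `m2`, `m2_df`, `m2_p`, `rmsea`, `cronbach_alpha`,
#'   `marginal_reliability`, `n`, `n_complete`.
#' @export
model_fit <- function(fit, m2 = TRUE, m2_margin_cap = 6000) {
  stopifnot(inherits(fit, "grm_fit"))
  values <- fit$values
  n <- fit$n_effective
  q <- sum(vapply(fit$bank$items, function(it) length(it$b) + 1L, integer(1)))
  minus2ll <- -2 * fit$loglik
  aic <- minus2ll + 2 * q
  bic <- minus2ll + q * log(n)
  m2v <- df2 <- p2 <- rmsea <- NA_real_
  cc <- stats::complete.cases(values)
  n_cc <- sum(cc)
  if (m2 && n_cc >= 10L) {
    res <- .m2_statistic(fit$bank$items, values[cc, , drop = FALSE], fit$grid,
                         margin_cap = m2_margin_cap)
    if (!is.null(res)) {
      m2v <- res$m2; df2 <- res$df; p2 <- res$p
      rmsea <- sqrt(max(0, (m2v - df2) / (df2 * n_cc)))
    }
  }
  resp <- response_matrix(values, C = fit$C, respondent_ids = fit$respondent_ids,
                          item_ids = fit$item_ids)
  structure(list(minus2ll = minus2ll, n_params = q, aic = aic, bic = bic,
                 m2 = m2v, m2_df = df2, m2_p = p2, rmsea = rmsea,
                 cronbach_alpha = cronbach_alpha(resp),
                 marginal_reliability = marginal_reliability(fit),
                 n = n, n_complete = n_cc),
            class = "model_fit_stats")
}

#' @export
print.model_fit_stats <- function(x, ...) {
  cat(sprintf("-2LL %.2f | AIC %.2f | BIC %.2f | alpha %.3f | marg. rel. %.3f\n",
              x$minus2ll, x$aic, x$bic, x$cronbach_alpha, x$marginal_reliability))
  if (is.finite(x$m2))
    cat(sprintf("M2 %.2f (df %d, p %.3g) | RMSEA %.3f\n", x$m2, x$m2_df, x$m2_p, x$rmsea))
  invisible(x)
}
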