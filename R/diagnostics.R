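# Lord-Wingersky recursion: distribution of the summed score over `items`
# at each grid point. Returns a (max_score + 1) x T matrix.
.score_distribution <- function(items, points) {
  smax <- sum(vapply(items, function(it) length(it$b), integer(1)))
  Tn <- length(points)
  f <- matrix(0, smax + 1L, Tn)
  f[1L, ] <- 1
  top <- 0L
  for (it in items) {
    P <- t(.cat_matrix(it$a, it$b, points))   # C x T
    C <- nrow(P)
    g <- matrix(0, top + C, Tn)
    for (k in seq_len(C))
      g[(k - 1L) + seq_len(top + 1L), ] <- g[(k - 1L) + seq_len(top + 1L), , drop = FALSE] +
        f[seq_len(top + 1L), , drop = FALSE] * rep(P[k, ], each = top + 1L)
    top <- top + C - 1L
    f[seq_len(top + 1L), ] <- g
  }
  f[seq_len(top + 1L), , drop = FALSE]
}

#' Orlando-Thissen S-X2 item fit
#'
#' For each item, respondents (complete cases) are grouped by their rest
#' score — the summed score over the other items — and the observed category
#' proportions in each group are compared with the model-expected
#' proportions, obtained by integrating the item's trace lines against the
#' recursive summed-score distribution of the remaining items. Adjacent
#' rest-score groups are merged until every expected cell reaches
#' `min_expected`. P-values are Benjamini-Hochberg adjusted across items.
#'
#' Summed scores require complete response vectors, so by default rows with
#' any missing response are dropped (`impute = "none"`). With
#' `impute = "eap"`, missing cells are instead filled deterministically
#' with the modal category of the respondent's posterior-predictive
#' distribution — a practical workaround for sparse complete cases on long
#' banks; it is a no-op on complete data.
#'
#' @param fit A converged [fit_grm()].
#' @param responses Optional [response_matrix()] (default: fitted data).
#' @param alpha_level Flag level on adjusted p-values (default 0.01).
#' @param min_expected Minimum expected count per cell before collapsing
#'   (default 1).
#' @param impute Missing-data handling: `"none"` (complete cases) or
#'   `"eap"` (deterministic posterior-modal fill).
#' @return Data frame with `item_id`, `sx2`, `df`, `p`, `p_adjusted`,
#'   `flagged`, `n_groups`.
#' @export
item_fit_sx2 <- function(fit, responses = NULL, alpha_level = 0.01, min_expected = 1,
                         impute = c("none", "eap")) {
  stopifnot(inherits(fit, "grm_fit"))
  impute <- match.arg(impute)
  values <- if (is.null(responses)) fit$values else responses$values
  if (impute == "eap" && anyNA(values)) values <- .impute_modal(fit, values)
  cc <- stats::complete.cases(values)
  values <- values[cc, , drop = FALSE]
  if (nrow(values) < 50L)
    stop("too few complete cases for S-X2; lower min_expected, impute, or pool data",
         call. = FALSE)
  items <- fit$bank$items
  grid <- fit$grid
  m <- length(items)
  out <- data.frame(item_id = names(items), sx2 = NA_real_, df = NA_integer_,
                    p = NA_real_, stringsAsFactors = FALSE)
  ngroups <- integer(m)
  for (j in seq_len(m)) {
    it <- items[[j]]
    C <- length(it$b) + 1L
    rest <- rowSums(values[, -j, drop = FALSE])
    frest <- .score_distribution(items[-j], grid$points)    # (S+1) x T
    Pj <- .cat_matrix(it$a, it$b, grid$points)              # T x C
    wf <- frest * rep(grid$weights, each = nrow(frest))     # joint over (s, t)
    denom <- rowSums(wf)                                    # P(rest = s)
    Ejk <- wf %*% Pj                                        # (S+1) x C, joint
    # observed counts by rest score
    smax <- nrow(frest) - 1L
    O <- matrix(0, smax + 1L, C)
    for (k in seq_len(C))
      O[, k] <- tabulate(rest[values[, j] == k - 1L] + 1L, nbins = smax + 1L)
    Ns <- rowSums(O)
    keep <- Ns > 0L
    O <- O[keep, , drop = FALSE]
    Econd <- (Ejk / pmax(denom, .P_EPS))[keep, , drop = FALSE]
    Ecnt <- Econd * Ns[keep]
    # collapse adjacent rest-score groups from the extremes inward
    gl <- .collapse_groups(O, Ecnt, min_expected)
    X2 <- sum((gl$O - gl$E)^2 / pmax(gl$E, .P_EPS))
    df <- nrow(gl$O) * (C - 1L) - C
    out$sx2[j] <- X2
    out$df[j] <- max(df, 1L)
    out$p[j] <- stats::pchisq(X2, max(df, 1L), lower.tail = FALSE)
    ngroups[j] <- nrow(gl$O)
  }
  adj <- bh_adjust(out$p, level = alpha_level)
  out$p_adjusted <- adj$p_adjusted
  out$flagged <- adj$reject
  out$n_groups <- ngroups
  out
}

# Deterministic modal posterior-predictive fill for missing cells.
.impute_modal <- function(fit, values) {
  W <- .posterior_weights(fit$bank$items, values, fit$grid)
  for (j in seq_len(ncol(values))) {
    mis <- which(is.na(values[, j]))
    if (!length(mis)) next
    it <- fit$bank$items[[j]]
    P <- .cat_matrix(it$a, it$b, fit$grid$points)       # T x C
    pred <- W[mis, , drop = FALSE] %*% P                # n_mis x C
    values[mis, j] <- max.col(pred, ties.method = "first") - 1L
  }
  values
}

# Merge adjacent rows (score groups) until all expected cells >= min_expected.
.collapse_groups <- function(O, E, min_expected) {
  repeat {
    if (nrow(O) <= 2L) break
    bad <- which(apply(E, 1L, min) < min_expected)
    if (!length(bad)) break
    # merge the offending row nearest an edge toward the interior
    r <- if (bad[1] <= nrow(O) - bad[length(bad)] + 1L) bad[1] else bad[length(bad)]
    to <- if (r == nrow(O)) r - 1L else r + 1L
    O[to, ] <- O[to, ] + O[r, ]
    E[to, ] <- E[to, ] + E[r, ]
    O <- O[-r, , drop = FALSE]
    E <- E[-r, , drop = FALSE]
  }
  list(O = O, E = E)
}

#' Benjamini-Hochberg multiplicity adjustment
#'
#' Step-up false-discovery-rate control; adjusted values come from
#' [stats::p.adjust()] and rejection means `adjusted < level`.
#'
#' @param pvalues Vector of p-values in `[0, 1]`.
#' @param level FDR level (default 0.01).
#' @return List with `p_adjusted` and logical `reject`.
#' @export
bh_adjust <- function(pvalues, level = 0.01) {
  if (!length(pvalues)) return(list(p_adjusted = numeric(0), reject = logical(0)))
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  adj <- stats::p.adjust(pvalues, method = "BH")
  list(p_adjusted = adj, reject = !is.na(adj) & adj < level)
}

#' Pairwise local-dependence statistics
#'
#' For every item pair, compares the observed joint category table with the
#' model-expected table (the fitted joint distribution integrated over the
#' latent-trait population by quadrature) via a Pearson X2, and reports the
#' approximately standardized value `(X2 - df) / sqrt(2 df)`. Values of 10 or more flag
#' likely local dependence; values in `[5, 10)` are reported as borderline
#' but never auto-flagged.
#'
#' @param fit A converged [fit_grm()].
#' @param responses Optional [response_matrix()] (default: fitted data).
#' @param flag_threshold Flag cut-off (default 10).
#' @param borderline Lower edge of the borderline band (default 5).
#' @param min_expected Expected-count floor; sparse rows/columns of a pair
#'   table are merged below it (default 1).
#' @return List of class `ld_matrix`: `statistic` (m x m symmetric, `NA`
#'   diagonal), `flagged` and `borderline` (logical matrices), and
#'   `pairs` (long-format data frame).
#' @export
local_dependence <- function(fit, responses = NULL, flag_threshold = 10,
                             borderline = 5, min_expected = 1) {
  stopifnot(inherits(fit, "grm_fit"))
  values <- if (is.null(responses)) fit$values else responses$values
  items <- fit$bank$items
  m <- length(items)
  if (m < 2L) stop("local dependence needs at least two items", call. = FALSE)
  grid <- fit$grid
  Plist <- lapply(items, function(it) .cat_matrix(it$a, it$b, grid$points))
  S <- matrix(NA_real_, m, m, dimnames = list(names(items), names(items)))
  for (j in seq_len(m - 1L)) {
    for (k in (j + 1L):m) {
      ok <- which(!is.na(values[, j]) & !is.na(values[, k]))
      if (!length(ok)) next
      Cj <- ncol(Plist[[j]]); Ck <- ncol(Plist[[k]])
      O <- matrix(0, Cj, Ck)
      tab <- table(factor(values[ok, j], levels = 0:(Cj - 1L)),
                   factor(values[ok, k], levels = 0:(Ck - 1L)))
      O[] <- as.numeric(tab)
      # expected: model joint distribution under the population prior
      E <- length(ok) * t(Plist[[j]] * grid$weights) %*% Plist[[k]]  # Cj x Ck
      cl <- .collapse_table(O, E, min_expected)
      X2 <- sum((cl$O - cl$E)^2 / pmax(cl$E, .P_EPS))
      df <- (nrow(cl$O) - 1L) * (ncol(cl$O) - 1L)
      if (df >= 1L) S[j, k] <- S[k, j] <- (X2 - df) / sqrt(2 * df)
    }
  }
  pairs <- which(upper.tri(S), arr.ind = TRUE)
  long <- data.frame(item_1 = rownames(S)[pairs[, 1]],
                     item_2 = colnames(S)[pairs[, 2]],
                     statistic = S[pairs], stringsAsFactors = FALSE)
  long <- long[order(-long$statistic), ]
  rownames(long) <- NULL
  structure(list(statistic = S,
                 flagged = !is.na(S) & S >= flag_threshold,
                 borderline = !is.na(S) & S >= borderline & S < flag_threshold,
                 flag_threshold = flag_threshold, borderline_band = c(borderline, flag_threshold),
                 pairs = long),
            class = "ld_matrix")
}

#' @export
print.ld_matrix <- function(x, ...) {
  nf <- sum(x$flagged, na.rm = TRUE) / 2
  nb <- sum(x$borderline, na.rm = TRUE) / 2
  cat(sprintf("<ld_matrix> %d items: %d flagged pairs (>= %.0f), %d borderline\n",
              nrow(x$statistic), nf, x$flag_threshold, nb))
  if (nf > 0) print(utils::head(x$pairs[x$pairs$statistic >= x$flag_threshold, ], 10))
  invisible(x)
}

# Merge sparse rows/columns of a two-way table until expected >= min_expected.
.collapse_table <- function(O, E, min_expected) {
  merge_dim <- function(O, E, margin) {
    repeat {
      dn <- dim(O)[margin]
      if (dn <= 2L) break
      sums <- if (margin == 1L) apply(E, 1L, min) else apply(E, 2L, min)
      bad <- which(sums < min_expected)
      if (!length(bad)) break
      r <- if (bad[1] <= dn - bad[length(bad)] + 1L) bad[1] else bad[length(bad)]
      to <- if (r == dn) r - 1L else r + 1L
      if (margin == 1L) {
        O[to, ] <- O[to, ] + O[r, ]; E[to, ] <- E[to, ] + E[r, ]
        O <- O[-r, , drop = FALSE]; E <- E[-r, , drop = FALSE]
      } else {
        O[, to] <- O[, to] + O[, r]; E[, to] <- E[, to] + E[, r]
        O <- O[, -r, drop = FALSE]; E <- E[, -r, drop = FALSE]
      }
    }
    list(O = O, E = E)
  }
  x <- merge_dim(O, E, 1L)
  x <- merge_dim(x$O, x$E, 2L)
  x
}

#' Cronbach's alpha
#'
#' Classical internal consistency, `(m/(m-1)) (1 - sum item variances /
#' total variance)`, computed from the pairwise-available covariance matrix
#' so incomplete responses are used without imputation.
#'
#' @param responses A [response_matrix()] (or numeric matrix).
#' @return Scalar alpha (`NA` if the total variance is zero).
#' @export
cronbach_alpha <- function(responses) {
  values <- if (inherits(responses, "response_matrix")) responses$values else as.matrix(responses)
  if (ncol(values) < 2L) stop("alpha needs at least two items", call. = FALSE)
  V <- stats::cov(values, use = "pairwise.complete.obs")
  tot <- sum(V)
  if (!is.finite(tot) || tot <= 0) return(NA_real_)
  m <- ncol(values)
  (m / (m - 1)) * (1 - sum(diag(V)) / tot)
}

#' Marginal reliability of the scale
#'
#' One minus the average EAP posterior variance of the latent trait under
#' the standard-normal population: the proportion of trait variance the
#' bank's scores retain.
#'
#' @param fit A converged [fit_grm()].
#' @param responses Optional [response_matrix()] (default: fitted data).
#' @return Scalar in `[0, 1]`.
#' @export
marginal_reliability <- function(fit, responses = NULL) {
  stopifnot(inherits(fit, "grm_fit"))
  if (is.null(responses))
    responses <- response_matrix(fit$values, C = fit$C,
                                 respondent_ids = fit$respondent_ids,
                                 item_ids = fit$item_ids)
  sc <- score_respondents(fit$bank, responses, fit$grid)
  1 - mean(sc$se^2)
}
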