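#' DIF workflow settings
#'
#' @param level Significance level for all Wald flags (default 0.01).
#' @param max_iterations Purification iteration cap (default 10).
#' @param grid_points,grid_range,tol,max_cycles Calibration settings used by
#'   the internal fits (slightly coarser defaults than [grm_control()]; DIF
#'   runs several calibrations).
#' @return A list of class `dif_control`.
#' @export
dif_control <- function(level = 0.01, max_iterations = 10L,
                        grid_points = 51L, grid_range = c(-5, 5),
                        tol = 5e-4, max_cycles = 300L) {
  stopifnot(level > 0, level < 1, max_iterations >= 1L)
  structure(list(level = level, max_iterations = as.integer(max_iterations),
                 grid_points = as.integer(grid_points),
                 grid_range = as.numeric(grid_range),
                 tol = tol, max_cycles = as.integer(max_cycles)),
            class = "dif_control")
}

# Multi-group EM: shared item parameters, reference trait fixed N(0,1),
# focal trait N(mu, sigma) estimated alongside the items. Used to place the
# two groups on one metric before per-group (candidate) estimation.
.mg_em <- function(vr, vf, C, ctrl) {
  pooled <- rbind(vr, vf)
  cl <- .collapse_categories(pooled, C, "error")
  nr <- nrow(vr)
  vr <- cl$values[seq_len(nr), , drop = FALSE]
  vf <- cl$values[-seq_len(nr), , drop = FALSE]
  m <- ncol(vr)
  pts <- seq(ctrl$grid_range[1], ctrl$grid_range[2], length.out = ctrl$grid_points)
  Ceff <- vapply(cl$maps, length, integer(1))
  items <- lapply(seq_len(m), function(j) {
    st <- .start_item(cl$values[, j], Ceff[j])
    grm_item(colnames(vr)[j], st$a, st$b)
  })
  mu <- 0; sigma <- 1
  wr <- stats::dnorm(pts); wr <- wr / sum(wr)
  for (cycle in seq_len(ctrl$max_cycles)) {
    wf <- stats::dnorm(pts, mu, sigma); wf <- wf / sum(wf)
    Wr <- .posterior_weights(items, vr, list(points = pts, weights = wr))
    Wf <- .posterior_weights(items, vf, list(points = pts, weights = wf))
    max_delta <- 0
    for (j in seq_len(m)) {
      R <- matrix(0, length(pts), Ceff[j])
      for (G in list(list(W = Wr, v = vr), list(W = Wf, v = vf))) {
        obs <- which(!is.na(G$v[, j]))
        if (!length(obs)) next
        Rg <- t(rowsum(G$W[obs, , drop = FALSE], group = G$v[obs, j], reorder = TRUE))
        R[, as.integer(colnames(Rg)) + 1L] <- R[, as.integer(colnames(Rg)) + 1L] + Rg
      }
      it <- items[[j]]
      opt <- stats::optim(.phi_from_ab(it$a, it$b), .mstep_obj, .mstep_grad,
                          R = R, points = pts, method = "BFGS",
                          control = list(maxit = 60, reltol = 1e-12))
      new <- .ab_from_phi(opt$par)
      max_delta <- max(max_delta, abs(new$a - it$a), max(abs(new$b - it$b)))
      items[[j]] <- grm_item(it$item_id, new$a, new$b)
    }
    Ei <- drop(Wf %*% pts)
    Vi <- drop(Wf %*% pts^2) - Ei^2
    mu_new <- mean(Ei)
    sig_new <- sqrt(mean(Vi + (Ei - mu_new)^2))
    max_delta <- max(max_delta, abs(mu_new - mu), abs(sig_new - sigma))
    mu <- mu_new; sigma <- sig_new
    if (max_delta < ctrl$tol) break
  }
  list(items = items, mu = mu, sigma = sigma)
}

# Wald chi-square for the parameter difference of one item between two
# converged fits. V starts as the sum of the item's OPG covariance blocks;
# the metric-alignment step (estimating the focal moments with the items
# anchored) cancels the shared location/scale sampling noise of the latent
# metric in the difference, so the two common-mode components are removed
# from V (location: d b / d mu = 1 on every threshold; scale:
# d(a, b) / d log sigma = (-a, b)). Without this correction the omnibus
# test is conservative by roughly a quarter of its chi-square scale.
.wald_item <- function(id, fit_r, fit_f, n_r, n_f) {
  block <- function(fit) {
    idx <- attr(fit$se, "index")
    cols <- idx$col[idx$item == id]
    list(V = attr(fit$se, "vcov")[cols, cols, drop = FALSE],
         par = idx$par[idx$item == id])
  }
  br <- block(fit_r); bf <- block(fit_f)
  ir <- fit_r$bank$items[[id]]; iff <- fit_f$bank$items[[id]]
  if (length(ir$b) != length(iff$b)) return(NULL)
  d <- c(iff$a - ir$a, iff$b - ir$b)
  V <- br$V + bf$V
  a_bar <- (ir$a + iff$a) / 2
  b_bar <- (ir$b + iff$b) / 2
  u <- c(0, rep(1, length(b_bar)))
  v <- c(-a_bar, b_bar)
  shared <- (1 / n_r + 1 / n_f) * (tcrossprod(u) + 0.5 * tcrossprod(v))
  V_corr <- V - shared
  if (all(eigen(V_corr, symmetric = TRUE, only.values = TRUE)$values > 0))
    V <- V_corr
  stat <- function(sel) {
    x2 <- tryCatch(drop(t(d[sel]) %*% solve(V[sel, sel, drop = FALSE], d[sel])),
                   error = function(e) NA_real_)
    c(chi2 = x2, df = length(sel),
      p = stats::pchisq(x2, length(sel), lower.tail = FALSE))
  }
  all_idx <- seq_along(d)
  list(omnibus = stat(all_idx), a = stat(1L), b = stat(all_idx[-1L]))
}

#' Classify the type of differential item functioning
#'
#' Applied to the constrained Wald tests of a flagged item: a significant
#' slope test means non-uniform DIF (the item-trait association itself
#' differs between groups, whatever the threshold test says); otherwise a
#' significant threshold test means uniform DIF; otherwise none.
#'
#' @param a_p P-value of the slope-difference test.
#' @param b_p P-value of the joint threshold-difference test.
#' @param level Significance level (default 0.01).
#' @return `"nonuniform"`, `"uniform"`, or `"none"`.
#' @export
classify_dif <- function(a_p, b_p, level = 0.01) {
  if (!is.na(a_p) && a_p < level) return("nonuniform")
  if (!is.na(b_p) && b_p < level) return("uniform")
  "none"
}

#' Two-group DIF scan with Wald tests and anchor purification
#'
#' Implements the all-items-anchor workflow: (1) with every item
#' constrained equal across groups, estimate the focal group's latent mean
#' and SD against the reference group's N(0,1); (2) fixing those moments,
#' estimate all item parameters separately per group and compute an omnibus
#' Wald chi-square per item on the stacked parameter difference (df = C);
#' (3) for omnibus-significant items, run constrained slope (df 1) and
#' threshold (df C-1) tests and classify uniform vs non-uniform DIF;
#' (4) purify: re-anchor on the non-flagged items, re-estimate the group
#' moments, and repeat until the flagged set stabilizes (union kept, with a
#' warning, if it oscillates; hard stop at `max_iterations`).
#'
#' Respondents with missing group labels are dropped from DIF only. Items
#' with an unobserved category in either group are excluded from testing,
#' with a warning.
#'
#' @param responses A [response_matrix()].
#' @param groups Factor/character vector, one entry per respondent, with two
#'   levels; the first level (or `"reference"`) is the reference group.
#'   `NA` allowed.
#' @param control A [dif_control()].
#' @return An object of class `dif_result`: `table` (per-item tests, flags,
#'   and type), `anchors`, `group_summary`, `iterations` (flag-set log),
#'   `fits` (final per-group [fit_grm()] objects), `converged`.
#' @export
dif_scan <- function(responses, groups, control = dif_control()) {
  stopifnot(inherits(responses, "response_matrix"))
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(responses$values))
  keep <- !is.na(groups)
  groups <- groups[keep]
  lev <- unique(groups)
  if ("reference" %in% lev) lev <- c("reference", setdiff(lev, "reference"))
  if (length(lev) != 2L) stop("exactly two group levels are required", call. = FALSE)
  values <- responses$values[keep, , drop = FALSE]
  vr <- values[groups == lev[1], , drop = FALSE]
  vf <- values[groups == lev[2], , drop = FALSE]
  if (nrow(vr) < 2L || nrow(vf) < 2L)
    stop("each group needs at least 2 respondents", call. = FALSE)
  C <- responses$C
  ids <- responses$item_ids

  # testable items: every pooled-observed category present in both groups
  testable <- vapply(seq_along(ids), function(j) {
    pooled <- stats::na.omit(c(vr[, j], vf[, j]))
    cats <- sort(unique(pooled))
    all(cats %in% vr[, j]) && all(cats %in% vf[, j])
  }, logical(1))
  if (!all(testable))
    warning(sprintf("items excluded from DIF (unobserved category in a group): %s",
                    paste(ids[!testable], collapse = ", ")))
  if (!any(testable)) stop("no testable items", call. = FALSE)

  gctrl <- function(mu, sd) grm_control(grid_points = control$grid_points,
                                        grid_range = control$grid_range,
                                        tol = control$tol, max_cycles = control$max_cycles,
                                        on_unobserved = "collapse",
                                        prior_mean = mu, prior_sd = sd)
  resp_r <- response_matrix(vr, C = C, item_ids = ids)
  resp_f <- response_matrix(vf, C = C, item_ids = ids)

  flagged <- character(0)
  seen <- list()
  iterations <- list()
  converged <- FALSE
  oscillated <- FALSE
  for (iter in seq_len(control$max_iterations)) {
    anchors <- setdiff(ids[testable], flagged)
    if (!length(anchors))
      stop("AnchorSetEmpty: every testable item is flagged for DIF", call. = FALSE)
    aidx <- match(anchors, ids)
    mg <- .mg_em(vr[, aidx, drop = FALSE], vf[, aidx, drop = FALSE], C, control)
    fit_r <- suppressWarnings(fit_grm(resp_r, gctrl(0, 1)))
    fit_f <- suppressWarnings(fit_grm(resp_f, gctrl(mg$mu, mg$sigma)))
    if (is.null(fit_r$se) || is.null(fit_f$se))
      stop("standard errors unavailable for a group fit; DIF tests impossible", call. = FALSE)
    tests <- stats::setNames(vector("list", length(ids)), ids)
    for (id in ids[testable])
      tests[[id]] <- .wald_item(id, fit_r, fit_f, nrow(vr), nrow(vf))
    pom <- vapply(tests, function(tt) if (is.null(tt)) NA_real_ else tt$omnibus[["p"]],
                  numeric(1))
    new_flagged <- ids[!is.na(pom) & pom < control$level]
    iterations[[iter]] <- new_flagged
    if (setequal(new_flagged, flagged) && iter > 1L) { converged <- TRUE; break }
    if (any(vapply(seen, setequal, logical(1), y = new_flagged)) ) {
      flagged <- sort(union(flagged, new_flagged))
      warning("purification oscillated; keeping the union of flagged sets")
      oscillated <- TRUE
      break
    }
    seen <- c(seen, list(flagged))
    flagged <- new_flagged
    if (!length(flagged) && iter == 1L) { converged <- TRUE; break }
  }
  if (!converged && !oscillated)
    warning("purification reached max_iterations without stabilizing")

  tab <- data.frame(item_id = ids, testable = testable,
                    chi2 = NA_real_, df = NA_integer_, p = NA_real_,
                    a_chi2 = NA_real_, a_df = NA_integer_, a_p = NA_real_,
                    b_chi2 = NA_real_, b_df = NA_integer_, b_p = NA_real_,
                    flagged = FALSE, dif_type = "none",
                    stringsAsFactors = FALSE)
  for (j in seq_along(ids)) {
    tt <- tests[[ids[j]]]
    if (is.null(tt)) next
    tab$chi2[j] <- tt$omnibus[["chi2"]]; tab$df[j] <- tt$omnibus[["df"]]
    tab$p[j] <- tt$omnibus[["p"]]
    tab$flagged[j] <- ids[j] %in% flagged
    if (tab$flagged[j]) {
      tab$a_chi2[j] <- tt$a[["chi2"]]; tab$a_df[j] <- tt$a[["df"]]; tab$a_p[j] <- tt$a[["p"]]
      tab$b_chi2[j] <- tt$b[["chi2"]]; tab$b_df[j] <- tt$b[["df"]]; tab$b_p[j] <- tt$b[["p"]]
      tab$dif_type[j] <- classify_dif(tab$a_p[j], tab$b_p[j], control$level)
    }
  }
  structure(list(table = tab,
                 anchors = setdiff(ids[testable], flagged),
                 group_summary = data.frame(
                   group = lev, n = c(nrow(vr), nrow(vf)),
                   theta_mean = c(0, mg$mu), theta_sd = c(1, mg$sigma)),
                 iterations = iterations,
                 fits = list(reference = fit_r, focal = fit_f),
                 level = control$level, converged = converged),
            class = "dif_result")
}

#' @export
print.dif_result <- function(x, ...) {
  nf <- sum(x$table$flagged)
  cat(sprintf("<dif_result> %d items, %d flagged at p < %.3g (%s)\n",
              nrow(x$table), nf, x$level,
              if (x$converged) "purification converged" else "purification incomplete"))
  cat(sprintf("focal group: mean %.3f, sd %.3f\n",
              x$group_summary$theta_mean[2], x$group_summary$theta_sd[2]))
  if (nf) print(x$table[x$table$flagged,
                        c("item_id", "chi2", "df", "p", "a_p", "b_p", "dif_type")])
  invisible(x)
}

#' Per-group item characteristic curves for a DIF item
#'
#' Returns both groups' category and cumulative curves on a common grid,
#' plus an area-between-curves DIF magnitude: the population-weighted mean
#' absolute difference in expected item score. With a pure threshold shift
#' downward, every focal cumulative curve lies above the reference curve; a
#' slope difference makes the curves cross at the matching threshold.
#'
#' @param ref_item,focal_item [grm_item()] parameter sets for the two groups.
#' @param grid A [theta_grid()].
#' @return Data frame `theta, group, category, prob, cumprob` with attribute
#'   `"area_between"`.
#' @export
group_icc_overlay <- function(ref_item, focal_item, grid = normal_grid()) {
  stopifnot(inherits(ref_item, "grm_item"), inherits(focal_item, "grm_item"),
            length(ref_item$b) == length(focal_item$b))
  C <- length(ref_item$b) + 1L
  build <- function(it, gname) {
    P <- .cat_matrix(it$a, it$b, grid$points)
    cum <- cbind(1, .cum_matrix(it$a, it$b, grid$points))
    data.frame(theta = rep(grid$points, C),
               group = gname,
               category = rep(0:(C - 1L), each = length(grid$points)),
               prob = as.vector(P),
               cumprob = as.vector(cum),
               stringsAsFactors = FALSE)
  }
  out <- rbind(build(ref_item, "reference"), build(focal_item, "focal"))
  es_r <- drop(.cat_matrix(ref_item$a, ref_item$b, grid$points) %*% (0:(C - 1L)))
  es_f <- drop(.cat_matrix(focal_item$a, focal_item$b, grid$points) %*% (0:(C - 1L)))
  attr(out, "area_between") <- sum(grid$weights * abs(es_f - es_r))
  out
}
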