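#' Remove flagged items from short-form consideration
#'
#' Applies the screening rules used when trimming an item bank: items with
#' significant misfit, items in locally dependent sets (keeping at most one
#' designated item per set — by default the highest-slope member), and items
#' with DIF are set aside. Overrides re-admit specific flagged items on
#' content grounds; every decision is recorded in the exclusion ledger.
#'
#' @param bank A [grm_bank()].
#' @param misfit Character vector of misfitting item ids.
#' @param ld_sets List of character vectors: locally dependent item sets.
#' @param dif Character vector of DIF-flagged item ids.
#' @param ld_keep Optional character vector naming the member to retain from
#'   each LD set; defaults to the highest-slope member of each set. A
#'   retained LD item is still excluded if it carries any other flag.
#' @param overrides Named character vector: item ids to retain despite
#'   flags, values giving the reason. Overriding an unflagged item warns and
#'   is a no-op.
#' @return List with `eligible` (character vector, bank order) and `ledger`
#'   (data frame `item_id, status, reasons`).
#' @export
exclude_flagged <- function(bank, misfit = character(0), ld_sets = list(),
                            dif = character(0), ld_keep = NULL,
                            overrides = character(0)) {
  stopifnot(inherits(bank, "grm_bank"))
  ids <- names(bank$items)
  bad <- setdiff(c(misfit, unlist(ld_sets), dif, names(overrides), ld_keep), ids)
  if (length(bad))
    stop(sprintf("flags reference unknown items: %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  slopes <- vapply(bank$items, `[[`, numeric(1), "a")
  reasons <- stats::setNames(vector("list", length(ids)), ids)
  add <- function(id, why) reasons[[id]] <<- c(reasons[[id]], why)
  for (id in intersect(misfit, ids)) add(id, "misfit")
  for (s in ld_sets) {
    keep <- if (!is.null(ld_keep)) intersect(ld_keep, s) else character(0)
    if (!length(keep)) keep <- s[which.max(slopes[s])]
    for (id in setdiff(s, keep[1])) add(id, "local_dependence")
  }
  for (id in intersect(dif, ids)) add(id, "dif")
  flagged <- ids[vapply(reasons, length, integer(1)) > 0L]
  not_flagged_overrides <- setdiff(names(overrides), flagged)
  if (length(not_flagged_overrides))
    warning(sprintf("override of unflagged item(s) ignored: %s",
                    paste(not_flagged_overrides, collapse = ", ")))
  retained <- intersect(names(overrides), flagged)
  eligible <- ids[!(ids %in% setdiff(flagged, retained))]
  ledger <- data.frame(
    item_id = ids,
    status = ifelse(ids %in% retained, "retained_by_override",
                    ifelse(ids %in% flagged, "excluded", "eligible")),
    reasons = vapply(ids, function(id) paste(reasons[[id]], collapse = "+"),
                     character(1)),
    stringsAsFactors = FALSE)
  ledger$reasons[ledger$status == "retained_by_override"] <-
    paste0(ledger$reasons[ledger$status == "retained_by_override"], ";override:",
           overrides[ledger$item_id[ledger$status == "retained_by_override"]])
  rownames(ledger) <- NULL
  list(eligible = eligible, ledger = ledger)
}

#' Rank bank items by discrimination
#'
#' Stable descending sort on the slope parameter; ties broken by item id
#' (ascending), so the ranking is deterministic whatever the input order.
#'
#' @param bank A [grm_bank()].
#' @return Data frame `rank, item_id, a`.
#' @export
rank_by_discrimination <- function(bank) {
  stopifnot(inherits(bank, "grm_bank"), length(bank$items) >= 1L)
  ids <- names(bank$items)
  a <- vapply(bank$items, `[[`, numeric(1), "a")
  ord <- order(-a, ids)
  data.frame(rank = seq_along(ids), item_id = ids[ord], a = unname(a[ord]),
             stringsAsFactors = FALSE)
}

#' Content-criterion coverage of a short form
#'
#' Counts how many criteria of a [content_map()] are assessed by at least
#' one item of the form.
#'
#' @param items Character vector of form item ids (or a `short_form`).
#' @param map A [content_map()].
#' @return List with `count` and `detail` (per-criterion data frame).
#' @export
dsm_coverage <- function(items, map) {
  stopifnot(inherits(map, "content_map"))
  if (!length(map$criterion_id)) stop("empty content map", call. = FALSE)
  if (inherits(items, "short_form")) items <- items$item_ids
  covered_by <- lapply(map$items, intersect, y = items)
  detail <- data.frame(criterion_id = map$criterion_id,
                       label = map$label,
                       covered = vapply(covered_by, length, integer(1)) > 0L,
                       items = vapply(covered_by, paste, character(1), collapse = "; "),
                       stringsAsFactors = FALSE)
  list(count = sum(detail$covered), detail = detail)
}

#' Assemble a fixed short form
#'
#' Two deterministic strategies codify the usual trade-off:
#' `"content_first"` walks the content map in criterion order and, for each
#' uncovered criterion, takes the highest-slope eligible item mapped to it,
#' then fills remaining slots by slope rank; `"precision_first"` takes the
#' top-slope eligible items, nudging near-ties (slopes within `tie_band`)
#' toward items that cover still-uncovered criteria.
#'
#' @param bank A [grm_bank()] (provides slopes).
#' @param eligible Character vector of eligible item ids.
#' @param map A [content_map()].
#' @param strategy `"content_first"` or `"precision_first"`.
#' @param size Target number of items (default 10).
#' @param name Form label.
#' @param tie_band Slope band treated as a near-tie by `"precision_first"`
#'   (default 0.05).
#' @return An object of class `short_form`: `name`, `item_ids`, `coverage`,
#'   `rationale` (per-item pick reason).
#' @export
build_form <- function(bank, eligible, map, strategy = c("content_first", "precision_first"),
                       size = 10L, name = NULL, tie_band = 0.05) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(bank, "grm_bank"), inherits(map, "content_map"))
  eligible <- intersect(names(bank$items), eligible)  # bank order
  if (size > length(eligible)) {
    warning(sprintf("only %d eligible items for a size-%d form", length(eligible), size))
    size <- length(eligible)
  }
  slopes <- vapply(bank$items, `[[`, numeric(1), "a")
  by_slope <- eligible[order(-slopes[eligible], eligible)]
  chosen <- character(0)
  why <- character(0)
  covers <- function(id) map$criterion_id[vapply(map$items, function(s) id %in% s, logical(1))]
  uncovered <- function() {
    done <- unique(unlist(lapply(chosen, covers)))
    setdiff(map$criterion_id, done)
  }
  if (strategy == "content_first") {
    for (ci in seq_along(map$criterion_id)) {
      if (length(chosen) >= size) break
      if (!(map$criterion_id[ci] %in% uncovered())) next
      cand <- setdiff(intersect(by_slope, map$items[[ci]]), chosen)
      if (!length(cand)) next
      chosen <- c(chosen, cand[1])
      why <- c(why, sprintf("covers %s", map$criterion_id[ci]))
    }
    for (id in setdiff(by_slope, chosen)) {
      if (length(chosen) >= size) break
      chosen <- c(chosen, id)
      why <- c(why, "slope fill")
    }
  } else {
    remaining <- by_slope
    while (length(chosen) < size && length(remaining)) {
      head_a <- slopes[remaining[1]]
      tied <- remaining[slopes[remaining] >= head_a - tie_band]
      unc <- uncovered()
      helps <- tied[vapply(tied, function(id) length(intersect(covers(id), unc)) > 0L,
                           logical(1))]
      pick <- if (length(helps)) helps[1] else remaining[1]
      chosen <- c(chosen, pick)
      why <- c(why, if (length(helps) && pick != remaining[1])
        "near-tie broken toward content" else "slope rank")
      remaining <- setdiff(remaining, pick)
    }
  }
  cov <- dsm_coverage(chosen, map)
  structure(list(name = if (is.null(name)) strategy else name,
                 item_ids = chosen,
                 coverage = cov$count,
                 coverage_detail = cov$detail,
                 rationale = data.frame(item_id = chosen, reason = why,
                                        stringsAsFactors = FALSE)),
            class = "short_form")
}

#' @export
print.short_form <- function(x, ...) {
  cat(sprintf("<short_form> %s: %d items, %d criteria covered\n",
              x$name, length(x$item_ids), x$coverage))
  cat(paste0("  ", x$item_ids, collapse = "\n"), "\n")
  invisible(x)
}

#' Compare candidate short forms on common data
#'
#' Refits each form's items (by marginal maximum likelihood) on the form's
#' columns of the response matrix and tabulates Cronbach's alpha, -2LL,
#' AIC, BIC, RMSEA and M2, plus the change in -2LL between successive rows
#' (reported only between nested forms, `NA` otherwise), and each form's
#' test information curve for overlay plots.
#'
#' @param forms List of `short_form` objects (and/or character vectors of
#'   item ids; a full-bank "form" is allowed).
#' @param responses A [response_matrix()] containing all form items.
#' @param control A [grm_control()] for the per-form fits.
#' @param grid A [theta_grid()] for the information curves.
#' @return List of class `form_comparison`: `table` (one row per form) and
#'   `tif` (long data frame `form, theta, information`).
#' @export
compare_forms <- function(forms, responses, control = grm_control(),
                          grid = normal_grid()) {
  stopifnot(is.list(forms), inherits(responses, "response_matrix"))
  forms <- lapply(seq_along(forms), function(i) {
    f <- forms[[i]]
    if (inherits(f, "short_form")) f
    else structure(list(name = paste0("form", i), item_ids = as.character(f),
                        coverage = NA_integer_), class = "short_form")
  })
  rows <- list()
  tif <- list()
  prev_items <- NULL
  prev_m2ll <- NA_real_
  for (f in forms) {
    sub <- subset_items(responses, f$item_ids)
    fit <- fit_grm(sub, control)
    mf <- model_fit(fit)
    delta <- if (!is.null(prev_items) &&
                 (all(f$item_ids %in% prev_items) || all(prev_items %in% f$item_ids)))
      prev_m2ll - mf$minus2ll else NA_real_
    rows[[f$name]] <- data.frame(
      form = f$name, n_items = length(f$item_ids),
      cronbach_alpha = mf$cronbach_alpha,
      aic = mf$aic, bic = mf$bic, minus2ll = mf$minus2ll,
      delta_minus2ll = delta,
      rmsea = mf$rmsea, m2 = mf$m2, m2_df = mf$m2_df,
      marginal_reliability = mf$marginal_reliability,
      coverage = f$coverage, stringsAsFactors = FALSE)
    ti <- test_information(fit$bank, grid$points)
    tif[[f$name]] <- data.frame(form = f$name, theta = ti$theta,
                                information = ti$information,
                                stringsAsFactors = FALSE)
    prev_items <- f$item_ids
    prev_m2ll <- mf$minus2ll
  }
  structure(list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
                 tif = do.call(rbind, c(tif, list(make.row.names = FALSE)))),
            class = "form_comparison")
}

#' @export
print.form_comparison <- function(x, ...) {
  print(x$table[, c("form", "n_items", "cronbach_alpha", "aic", "bic",
                    "minus2ll", "delta_minus2ll", "rmsea", "coverage")])
  invisible(x)
}
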