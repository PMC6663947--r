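#' Read a wide-format response CSV
#'
#' Expects a header row of item ids, a first column of respondent ids, and
#' integer category codes in the cells; blank cells are missing. Codes are
#' remapped to the internal 0-based convention via `origin` (files coded
#' 1..C use `origin = 1`).
#'
#' @param path CSV path.
#' @param origin Integer code of the lowest category in the file (default 0).
#' @param C Number of categories; inferred from the data when `NULL`.
#' @return A [response_matrix()].
#' @export
read_responses <- function(path, origin = 0L, C = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (ncol(df) < 2L) stop("need a respondent-id column plus at least one item", call. = FALSE)
  ids <- df[[1]]
  raw <- as.matrix(df[, -1, drop = FALSE])
  raw[!nzchar(trimws(raw))] <- NA
  bad <- which(!is.na(raw) & !grepl("^-?[0-9]+$", trimws(raw)), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-integer response at row %d, column '%s'",
                 bad[1, 1], colnames(raw)[bad[1, 2]]), call. = FALSE)
  vals <- matrix(as.integer(raw), nrow(raw), ncol(raw),
                 dimnames = dimnames(raw)) - as.integer(origin)
  obs <- vals[!is.na(vals)]
  if (length(obs) && any(obs < 0L))
    stop(sprintf("category code below origin %d", origin), call. = FALSE)
  if (!is.null(C) && length(obs) && any(obs > C - 1L))
    stop(sprintf("category code exceeds C-1 = %d after origin shift", C - 1L),
         call. = FALSE)
  response_matrix(vals, C = C, respondent_ids = ids, item_ids = colnames(raw))
}

#' Write a response matrix as wide CSV
#'
#' Inverse of [read_responses()]: missing responses become blank cells.
#'
#' @param responses A [response_matrix()].
#' @param path Output path.
#' @param origin Code to assign the lowest category on disk (default 0).
#' @return `path`, invisibly.
#' @export
write_responses <- function(responses, path, origin = 0L) {
  stopifnot(inherits(responses, "response_matrix"))
  out <- as.data.frame(responses$values + as.integer(origin))
  names(out) <- responses$item_ids
  out <- cbind(data.frame(respondent_id = responses$respondent_ids,
                          stringsAsFactors = FALSE), out)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Filter respondents by response time
#'
#' Drops respondents who answered implausibly fast: mean response time
#' under `mean_cutoff` seconds, or `run_cutoff` or more consecutive items
#' each under `mean_cutoff` seconds.
#'
#' @param responses A [response_matrix()].
#' @param rt Numeric matrix of per-response times in seconds, same
#'   dimensions as the responses; `NA` allowed.
#' @param mean_cutoff Fast-response threshold in seconds (default 1).
#' @param run_cutoff Length of a disqualifying fast run (default 10).
#' @return List with `responses` (filtered), `removed` (ledger data frame
#'   `respondent_id, reason`), and `kept` (logical vector).
#' @export
rt_filter <- function(responses, rt, mean_cutoff = 1.0, run_cutoff = 10L) {
  stopifnot(inherits(responses, "response_matrix"))
  rt <- as.matrix(rt)
  if (!all(dim(rt) == dim(responses$values)))
    stop("response-time matrix dimensions do not match responses", call. = FALSE)
  if (any(rt < 0, na.rm = TRUE)) stop("response times must be nonnegative", call. = FALSE)
  mean_rt <- rowMeans(rt, na.rm = TRUE)
  fast_mean <- is.finite(mean_rt) & mean_rt < mean_cutoff
  longest_run <- apply(rt, 1L, function(r) {
    fast <- !is.na(r) & r < mean_cutoff
    if (!any(fast)) return(0L)
    max(rle(fast)$lengths[rle(fast)$values])
  })
  fast_run <- longest_run >= run_cutoff
  drop_ <- fast_mean | fast_run
  reason <- ifelse(fast_mean & fast_run, "mean_rt+fast_run",
                   ifelse(fast_mean, "mean_rt", "fast_run"))
  removed <- data.frame(respondent_id = responses$respondent_ids[drop_],
                        reason = reason[drop_], stringsAsFactors = FALSE)
  kept <- !drop_
  if (!any(kept)) stop("response-time filter removed every respondent", call. = FALSE)
  filtered <- response_matrix(responses$values[kept, , drop = FALSE], C = responses$C,
                              respondent_ids = responses$respondent_ids[kept],
                              item_ids = responses$item_ids)
  list(responses = filtered, removed = removed, kept = kept)
}

#' Run the full scale-development pipeline
#'
#' Orchestrates the analysis end to end: optional response-time cleaning,
#' GRM calibration, item fit, local dependence, DIF (when group labels are
#' supplied), flag-based exclusion, short-form construction under both
#' strategies, and form comparison. Writes a JSON report, parameter CSV,
#' and a Markdown summary into `output_dir` when given; outputs are
#' deterministic functions of the inputs.
#'
#' @param responses A [response_matrix()].
#' @param map A [content_map()].
#' @param groups Optional two-level group labels for DIF.
#' @param rt Optional response-time matrix (enables [rt_filter()]).
#' @param control A [grm_control()] for the main calibration.
#' @param dif_ctrl A [dif_control()].
#' @param alpha_level Flag level for item fit (default 0.01).
#' @param ld_threshold LD flag threshold (default 10).
#' @param form_size Short-form size (default 10).
#' @param overrides Named character vector of content-based retention
#'   overrides, passed to [exclude_flagged()].
#' @param output_dir Optional directory for report files.
#' @return List of class `pipeline_result` with every stage's output.
#' @export
run_pipeline <- function(responses, map, groups = NULL, rt = NULL,
                         control = grm_control(), dif_ctrl = dif_control(),
                         alpha_level = 0.01, ld_threshold = 10,
                         form_size = 10L, overrides = character(0),
                         output_dir = NULL) {
  stopifnot(inherits(responses, "response_matrix"), inherits(map, "content_map"))
  stages <- character(0)
  removed <- NULL
  if (!is.null(rt)) {
    fl <- rt_filter(responses, rt)
    if (!is.null(groups)) groups <- groups[fl$kept]
    responses <- fl$responses
    removed <- fl$removed
    stages <- c(stages, sprintf("rt_filter: removed %d respondents", nrow(removed)))
  }
  fit <- fit_grm(responses, control)
  stages <- c(stages, sprintf("calibration: %d cycles, %s", fit$n_cycles,
                              if (fit$converged) "converged" else "NOT converged"))
  sx2 <- item_fit_sx2(fit, alpha_level = alpha_level, impute = "eap")
  ld <- local_dependence(fit, flag_threshold = ld_threshold)
  mf <- model_fit(fit)
  dif <- NULL
  dif_items <- character(0)
  if (!is.null(groups)) {
    dif <- dif_scan(responses, groups, dif_ctrl)
    dif_items <- dif$table$item_id[dif$table$flagged]
    stages <- c(stages, sprintf("dif: %d flagged", length(dif_items)))
  } else {
    stages <- c(stages, "dif: skipped (no group labels)")
  }
  ld_sets <- .ld_components(ld)
  excl <- exclude_flagged(fit$bank, misfit = sx2$item_id[sx2$flagged],
                          ld_sets = ld_sets, dif = dif_items,
                          overrides = overrides)
  sf1 <- build_form(fit$bank, excl$eligible, map, "content_first", form_size,
                    name = "content_first")
  sf2 <- build_form(fit$bank, excl$eligible, map, "precision_first", form_size,
                    name = "precision_first")
  comparison <- compare_forms(list(sf1, sf2), responses, control)
  result <- structure(list(fit = fit, item_fit = sx2, ld = ld, model_fit = mf,
                           dif = dif, exclusions = excl,
                           forms = list(sf1, sf2), comparison = comparison,
                           removed = removed, stages = stages,
                           settings = list(alpha_level = alpha_level,
                                           ld_threshold = ld_threshold,
                                           form_size = form_size)),
                      class = "pipeline_result")
  if (!is.null(output_dir)) .write_report(result, output_dir)
  result
}

# Connected components of the flagged LD pairs.
.ld_components <- function(ld) {
  flg <- ld$flagged
  ids <- rownames(flg)
  parent <- stats::setNames(ids, ids)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  idx <- which(flg & upper.tri(flg), arr.ind = TRUE)
  if (!nrow(idx)) return(list())
  for (r in seq_len(nrow(idx)))
    parent[[find(ids[idx[r, 2]])]] <- find(ids[idx[r, 1]])
  involved <- unique(c(ids[idx[, 1]], ids[idx[, 2]]))
  unname(split(involved, vapply(involved, find, character(1))))
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  for (s in x$stages) cat(" -", s, "\n")
  cat(sprintf(" - item fit: %d flagged | LD pairs: %d | eligible: %d\n",
              sum(x$item_fit$flagged), sum(x$ld$flagged, na.rm = TRUE) / 2,
              sum(x$exclusions$ledger$status != "excluded")))
  print(x$comparison)
  invisible(x)
}

.write_report <- function(result, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(coef_table(result$fit),
                   file.path(output_dir, "parameters.csv"), row.names = FALSE)
  report <- list(
    settings = result$settings,
    stages = result$stages,
    model_fit = unclass(result$model_fit),
    item_fit = result$item_fit,
    ld_pairs = result$ld$pairs[!is.na(result$ld$pairs$statistic) &
                                 result$ld$pairs$statistic >= result$ld$borderline_band[1], ],
    dif = if (!is.null(result$dif)) result$dif$table else NULL,
    exclusions = result$exclusions$ledger,
    forms = lapply(result$forms, function(f)
      list(name = f$name, items = f$item_ids, coverage = f$coverage)),
    comparison = result$comparison$table)
  jsonlite::write_json(report, file.path(output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  md <- c("# Scale development report", "",
          "## Stages", paste0("- ", result$stages), "",
          "## Item diagnostics",
          "", .md_table(merge(coef_table(result$fit)[, c("item_id", "a")],
                              result$item_fit[, c("item_id", "sx2", "df", "p_adjusted", "flagged")],
                              by = "item_id", sort = FALSE)), "",
          "## Form comparison", "", .md_table(result$comparison$table))
  writeLines(md, file.path(output_dir, "summary.md"))
  invisible(output_dir)
}

# Minimal Markdown table renderer.
.md_table <- function(df) {
  fmt <- function(x) {
    if (is.numeric(x)) formatC(x, digits = 4, format = "g") else as.character(x)
  }
  cells <- vapply(df, fmt, character(nrow(df)))
  if (is.null(dim(cells))) cells <- matrix(cells, nrow = 1L)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(cells, 1L, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, rows)
}
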