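#' Item parameters for the graded response model
#'
#' An item is described by a positive slope (discrimination) `a` and a strictly
#' increasing vector of thresholds (severities) `b`. An item with `C` response
#' categories (coded `0 .. C-1`) has `C - 1` thresholds: `b[j]` is the latent
#' trait level at which the probability of responding in category `j` or
#' higher equals 0.5.
#'
#' @param item_id Character scalar, unique item identifier.
#' @param a Positive slope parameter, in units of the latent-trait SD.
#' @param b Numeric vector of thresholds, strictly increasing, length `C - 1`.
#'
#' @return An object of class `grm_item`.
#' @examples
#' it <- grm_item("hopeless", a = 4.46, b = c(0.38, 0.97, 1.53, 2.23))
#' ncat(it)
#' @export
grm_item <- function(item_id, a, b) {
  stopifnot(is.character(item_id), length(item_id) == 1L, nzchar(item_id))
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a <= 0)
    stop("slope `a` must be a single positive finite number", call. = FALSE)
  b <- as.numeric(b)
  if (length(b) < 1L || anyNA(b) || any(!is.finite(b)))
    stop("thresholds `b` must be finite and non-empty (C >= 2)", call. = FALSE)
  if (length(b) > 1L && any(diff(b) <= 0))
    stop("thresholds `b` must be strictly increasing", call. = FALSE)
  structure(list(item_id = item_id, a = as.numeric(a), b = b),
            class = "grm_item")
}

#' Number of response categories of an item
#' @param x A `grm_item`.
#' @return Integer, `length(x$b) + 1`.
#' @export
ncat <- function(x) UseMethod("ncat")

#' @export
ncat.grm_item <- function(x) length(x$b) + 1L

#' @export
print.grm_item <- function(x, ...) {
  cat(sprintf("<grm_item> %s  a = %.3f  b = (%s)\n",
              x$item_id, x$a, paste(sprintf("%.3f", x$b), collapse = ", ")))
  invisible(x)
}

#' An ordered bank of GRM items
#'
#' A bank bundles calibrated (or generating) item parameters with optional
#' per-item metadata: stem text, subdomain tag, and response-scale labels.
#'
#' @param items List of [grm_item()] objects (or a single item).
#' @param stems Optional character vector of item stems (recycled names).
#' @param subdomain Optional character vector of subdomain tags.
#' @param scale_labels Optional character vector naming the response scale
#'   (e.g. `"frequency"` or `"severity"`); metadata only, never used in
#'   estimation.
#'
#' @return An object of class `grm_bank`: a list with `items` (named list)
#'   and `meta` (data frame).
#' @export
grm_bank <- function(items, stems = NULL, subdomain = NULL, scale_labels = NULL) {
  if (inherits(items, "grm_item")) items <- list(items)
  stopifnot(length(items) >= 1L)
  ok <- vapply(items, inherits, logical(1), "grm_item")
  if (!all(ok)) stop("all elements of `items` must be grm_item objects", call. = FALSE)
  ids <- vapply(items, `[[`, character(1), "item_id")
  if (anyDuplicated(ids)) stop("item ids must be unique", call. = FALSE)
  names(items) <- ids
  meta <- data.frame(
    item_id = ids,
    stem = if (is.null(stems)) ids else as.character(stems),
    subdomain = if (is.null(subdomain)) NA_character_ else as.character(subdomain),
    scale = if (is.null(scale_labels)) "frequency" else as.character(scale_labels),
    stringsAsFactors = FALSE
  )
  structure(list(items = items, meta = meta), class = "grm_bank")
}

#' @export
length.grm_bank <- function(x) length(x$items)

#' @export
print.grm_bank <- function(x, ...) {
  cat(sprintf("<grm_bank> %d items, categories: %s\n", length(x$items),
              paste(sort(unique(vapply(x$items, ncat, integer(1)))), collapse = "/")))
  invisible(x)
}

#' @export
`[.grm_bank` <- function(x, i) {
  items <- x$items[i]
  if (anyNA(names(items))) stop("unknown item in bank subset", call. = FALSE)
  grm_bank(items, stems = x$meta$stem[match(names(items), x$meta$item_id)],
           subdomain = x$meta$subdomain[match(names(items), x$meta$item_id)],
           scale_labels = x$meta$scale[match(names(items), x$meta$item_id)])
}

#' Coerce a bank to a parameter data frame
#'
#' @param x A `grm_bank`.
#' @param ... Unused.
#' @return Data frame with columns `item_id`, `a`, `b1`, `b2`, ... (ragged
#'   banks padded with `NA`).
#' @export
as.data.frame.grm_bank <- function(x, ...) {
  nb <- max(vapply(x$items, function(it) length(it$b), integer(1)))
  rows <- lapply(x$items, function(it) {
    b <- c(it$b, rep(NA_real_, nb - length(it$b)))
    c(a = it$a, stats::setNames(b, paste0("b", seq_len(nb))))
  })
  out <- as.data.frame(do.call(rbind, rows))
  out <- cbind(data.frame(item_id = names(x$items), stringsAsFactors = FALSE), out)
  rownames(out) <- NULL
  out
}

#' Build a bank from a parameter data frame
#'
#' Inverse of [as.data.frame.grm_bank()]: expects columns `item_id`, `a`,
#' `b1`, `b2`, ... Trailing `NA` thresholds are dropped per item.
#'
#' @param df Data frame of parameters.
#' @param stems,subdomain,scale_labels Optional metadata vectors.
#' @return A [grm_bank()].
#' @export
bank_from_frame <- function(df, stems = NULL, subdomain = NULL, scale_labels = NULL) {
  bcols <- grep("^b[0-9]+$", names(df), value = TRUE)
  bcols <- bcols[order(as.integer(sub("^b", "", bcols)))]
  items <- lapply(seq_len(nrow(df)), function(i) {
    b <- as.numeric(df[i, bcols])
    b <- b[!is.na(b)]
    grm_item(as.character(df$item_id[i]), df$a[i], b)
  })
  grm_bank(items, stems = stems, subdomain = subdomain, scale_labels = scale_labels)
}

#' Quadrature grid over the latent trait
#'
#' @param points Strictly increasing numeric vector of latent-trait nodes.
#' @param weights Positive weights; normalized to sum to 1.
#' @return An object of class `theta_grid`.
#' @seealso [normal_grid()] for the default standard-normal grid.
#' @export
theta_grid <- function(points, weights) {
  points <- as.numeric(points); weights <- as.numeric(weights)
  stopifnot(length(points) == length(weights), length(points) >= 1L)
  if (length(points) > 1L && any(diff(points) <= 0))
    stop("grid points must be strictly increasing", call. = FALSE)
  if (any(weights <= 0)) stop("grid weights must be positive", call. = FALSE)
  weights <- weights / sum(weights)
  structure(list(points = points, weights = weights), class = "theta_grid")
}

#' Equally spaced grid with normalized normal weights
#'
#' The default quadrature for marginal maximum likelihood: `n` equally spaced
#' nodes on `range`, weighted by the `N(mean, sd)` density and renormalized.
#'
#' @param n Number of nodes (default 121; enough to resolve the narrow
#'   posteriors of long, highly discriminating banks).
#' @param range Length-2 numeric range (default `c(-6, 6)`).
#' @param mean,sd Population mean and SD of the latent trait (default 0, 1).
#' @return A [theta_grid()].
#' @export
normal_grid <- function(n = 121L, range = c(-6, 6), mean = 0, sd = 1) {
  pts <- seq(range[1], range[2], length.out = n)
  theta_grid(pts, stats::dnorm(pts, mean, sd))
}

#' Respondent-by-item polytomous response matrix
#'
#' Wraps an integer matrix of category codes `0 .. C-1` with `NA` for missing
#' responses, plus respondent and item identifiers.
#'
#' @param values Integer matrix (respondents x items); `NA` = missing.
#' @param C Number of response categories; inferred as `max(values) + 1`
#'   when omitted.
#' @param respondent_ids,item_ids Optional identifier vectors; defaults are
#'   generated (`r1..rn` / colnames or `item1..itemm`).
#' @return An object of class `response_matrix`.
#' @export
response_matrix <- function(values, C = NULL, respondent_ids = NULL, item_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("response matrix must have at least one respondent and one item", call. = FALSE)
  obs <- values[!is.na(values)]
  if (length(obs) && any(obs < 0L))
    stop("category codes must be non-negative (0-based)", call. = FALSE)
  if (is.null(C)) C <- max(obs, 0L) + 1L
  C <- as.integer(C)
  if (C < 2L) stop("C must be >= 2", call. = FALSE)
  if (length(obs) && any(obs > C - 1L))
    stop(sprintf("category code exceeds C-1 = %d", C - 1L), call. = FALSE)
  if (is.null(respondent_ids)) respondent_ids <- paste0("r", seq_len(nrow(values)))
  if (is.null(item_ids)) item_ids <- colnames(values)
  if (is.null(item_ids)) item_ids <- paste0("item", seq_len(ncol(values)))
  dimnames(values) <- list(NULL, item_ids)
  structure(list(values = values, C = C,
                 respondent_ids = as.character(respondent_ids),
                 item_ids = as.character(item_ids)),
            class = "response_matrix")
}

#' @export
dim.response_matrix <- function(x) dim(x$values)

#' @export
print.response_matrix <- function(x, ...) {
  nmiss <- sum(is.na(x$values))
  cat(sprintf("<response_matrix> %d respondents x %d items, C = %d, %.1f%% missing\n",
              nrow(x$values), ncol(x$values), x$C,
              100 * nmiss / length(x$values)))
  invisible(x)
}

#' Subset the columns (items) of a response matrix
#' @param x A `response_matrix`.
#' @param items Item ids or column indices to keep.
#' @return A `response_matrix` on the selected items (same C).
#' @export
subset_items <- function(x, items) {
  stopifnot(inherits(x, "response_matrix"))
  idx <- if (is.character(items)) match(items, x$item_ids) else as.integer(items)
  if (anyNA(idx)) stop("unknown item id in subset", call. = FALSE)
  response_matrix(x$values[, idx, drop = FALSE], C = x$C,
                  respondent_ids = x$respondent_ids,
                  item_ids = x$item_ids[idx])
}
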