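#' Content-criterion map
#'
#' Associates an ordered list of content criteria (for depression short
#' forms, the 11 DSM-5 diagnostic criteria) with the item ids that assess
#' each criterion. Criterion order matters: deterministic short-form
#' construction walks criteria in this order.
#'
#' @param criterion_id Character vector of unique criterion ids, in order.
#' @param label Character vector of human-readable labels.
#' @param items List (same length) of character vectors of item ids; empty
#'   vectors are allowed (criteria no bank item can cover).
#' @return An object of class `content_map`.
#' @export
content_map <- function(criterion_id, label, items) {
  stopifnot(length(criterion_id) == length(label),
            length(criterion_id) == length(items))
  if (anyDuplicated(criterion_id)) stop("criterion ids must be unique", call. = FALSE)
  structure(list(criterion_id = as.character(criterion_id),
                 label = as.character(label),
                 items = lapply(items, as.character)),
            class = "content_map")
}

#' @export
print.content_map <- function(x, ...) {
  cat(sprintf("<content_map> %d criteria, %d mapped items\n",
              length(x$criterion_id), length(unique(unlist(x$items)))))
  invisible(x)
}

#' Packaged 51-item depression bank fixture
#'
#' Returns the published calibration of the 51 depression items considered
#' for the PROMIS depression bank, transcribed once and frozen under test:
#' slopes and thresholds, item-fit flags, local-dependence partner sets,
#' gender-DIF flags, the DSM-5 content map, and the two 10-item short-form
#' item lists. These parameters are didactic, not official scoring
#' parameters.
#'
#' The content map follows the published criterion rows, with one documented
#' choice: "I withdrew from other people" is counted under the clinically
#' significant impairment criterion (social withdrawal), alongside the two
#' distress items.
#'
#' @return A list with elements `bank` ([grm_bank()], 51 items),
#'   `table` (raw data frame), `misfit_items`, `ld_partners` (named list of
#'   character vectors), `ld_sets` (connected components), `dif_items`,
#'   `dsm_map` ([content_map()]), `sf1_items`, `sf2_items`.
#' @export
depression_fixture <- function() {
  csv <- system.file("extdata", "depression_bank51.csv", package = "grmbank",
                     mustWork = TRUE)
  tab <- utils::read.csv(csv, stringsAsFactors = FALSE)
  # normalize any unicode minus that survives transcription
  for (cc in c("a", paste0("b", 1:4)))
    if (is.character(tab[[cc]]))
      tab[[cc]] <- as.numeric(gsub("−", "-", tab[[cc]]))
  items <- lapply(seq_len(nrow(tab)), function(i)
    grm_item(tab$item_id[i], tab$a[i],
             c(tab$b1[i], tab$b2[i], tab$b3[i], tab$b4[i])))
  bank <- grm_bank(items, stems = tab$item_id, scale_labels = tab$scale)

  id_of <- function(nos) tab$item_id[match(nos, tab$item_no)]
  ld_partners <- lapply(seq_len(nrow(tab)), function(i) {
    if (!nzchar(tab$ld_partners[i])) return(character(0))
    id_of(as.integer(strsplit(tab$ld_partners[i], ";")[[1]]))
  })
  names(ld_partners) <- tab$item_id
  ld_partners <- ld_partners[vapply(ld_partners, length, integer(1)) > 0L]

  # connected components of the LD partner graph (union-find)
  parent <- stats::setNames(tab$item_id, tab$item_id)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (id in names(ld_partners))
    for (p in ld_partners[[id]]) parent[[find(p)]] <- find(id)
  involved <- names(ld_partners)
  roots <- vapply(involved, find, character(1))
  ld_sets <- unname(split(involved, roots))
  ld_sets <- lapply(ld_sets, function(s) s[order(match(s, tab$item_id))])
  ld_sets <- ld_sets[order(vapply(ld_sets, function(s) match(s[1], tab$item_id), integer(1)))]

  mp <- jsonlite::read_json(system.file("extdata", "dsm_content_map.json",
                                        package = "grmbank", mustWork = TRUE),
                            simplifyVector = TRUE)
  dsm_map <- content_map(mp$criteria$criterion_id, mp$criteria$label,
                         lapply(mp$criteria$item_nos, id_of))

  list(bank = bank,
       table = tab,
       misfit_items = tab$item_id[tab$misfit == 1L],
       ld_partners = ld_partners,
       ld_sets = ld_sets,
       dif_items = tab$item_id[tab$dif_flag == 1L],
       dsm_map = dsm_map,
       sf1_items = id_of(mp$short_form_1),
       sf2_items = id_of(mp$short_form_2))
}
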