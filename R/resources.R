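#' Count resources used during visits
#'
#' Tallies ESI-style "resources" from each record's observed service items.
#' Items are grouped (all blood tests are one resource; each imaging
#' modality, ECG, IV fluids and parenteral medications count separately;
#' a complex procedure counts two): a group contributes its configured
#' count once, no matter how many of its member items were used. Items in
#' `excluded_items` (oral medications, point-of-care glucose) never count.
#' The tally is retrospective: only services actually recorded enter it.
#'
#' @param records Canonical visit tibble.
#' @param defs Resource definitions (the `resources` element of an
#'   `esin_criteria` object).
#' @param unknown_items Policy for service items not covered by `defs`:
#'   `"warn"` (default) ignores them with a one-off warning, `"strict"`
#'   raises an error.
#' @return Tibble with one row per record: `resource_total` and
#'   `resource_items`, a pipe-delimited `group:item` audit of what counted.
#' @export
#' @examples
#' cfg <- load_criteria()
#' recs <- empty_records()[0, ]
#' recs[1, "services"] <- "CBC|URINE|XRAY"  # two lab items count once
#' count_resources(coerce_records_public(recs), cfg$resources)
count_resources <- function(records, defs, unknown_items = c("warn", "strict")) {
  unknown_items <- match.arg(unknown_items)
  validate_resource_defs(defs)
  items <- split_services(records$services)
  known <- c(unlist(lapply(defs$groups, `[[`, "items")),
             unlist(defs$excluded_items))
  seen <- unique(unlist(items))
  stray <- setdiff(seen, known)
  if (length(stray)) {
    msg <- sprintf("service item(s) unknown to resource definitions: %s",
                   paste(stray, collapse = ", "))
    if (unknown_items == "strict") abort(msg) else warn(msg)
  }
  total <- rep(0L, nrow(records))
  itemized <- rep("", nrow(records))
  for (grp in defs$groups) {
    members <- setdiff(unlist(grp$items), unlist(defs$excluded_items))
    hits <- lapply(items, intersect, members)
    fired <- lengths(hits) > 0
    total <- total + ifelse(fired, as.integer(grp$count), 0L)
    piece <- ifelse(fired,
                    paste0(grp$name, ":",
                           vapply(hits, paste, character(1), collapse = ",")),
                    "")
    itemized <- ifelse(fired,
                       ifelse(nzchar(itemized), paste(itemized, piece, sep = "|"), piece),
                       itemized)
  }
  tibble::tibble(resource_total = as.integer(total), resource_items = itemized)
}

validate_resource_defs <- function(defs) {
  if (is.null(defs$groups) || length(defs$groups) == 0) {
    abort("resource definitions must contain at least one group")
  }
  all_items <- unlist(lapply(defs$groups, `[[`, "items"))
  dup <- unique(all_items[duplicated(all_items)])
  if (length(dup)) {
    abort(sprintf("service item(s) assigned to more than one resource group: %s",
                  paste(dup, collapse = ", ")))
  }
  counts <- vapply(defs$groups, function(g) as.numeric(g$count), numeric(1))
  if (any(is.na(counts) | counts < 0)) {
    abort("every resource group needs a non-negative count")
  }
  invisible(defs)
}

#' @rdname validate_records
#' @param records Tibble with (a subset of) canonical columns.
#' @details `coerce_records_public()` pads a partial tibble out to the full
#'   canonical column set with missing values and canonical types; handy for
#'   building small test cohorts by hand.
#' @export
coerce_records_public <- function(records) {
  coerce_records(records)
}
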