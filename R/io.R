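#' Load a per-year raw-file dialect
#'
#' Year-to-year drift in the raw survey files (variable renames, sentinel
#' codes, implied decimals, which service indicators exist) is absorbed by
#' per-year dialect files shipped as data under
#' `system.file("extdata", "dialects", package = "esin")`, not by code.
#' A dialect lists, for each canonical field, the year's raw variable name,
#' fixed-width column width, type, sentinel codes that mean "missing", and
#' any scale factor (e.g. temperature stored with an implied decimal), plus
#' the year's service-indicator fields.
#'
#' @param year Survey year (2010--2015 supported by the shipped dialects).
#' @param path Optional path to a dialect YAML, overriding the shipped one.
#' @return A list of class `esin_dialect`.
#' @export
load_dialect <- function(year, path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "dialects",
                        sprintf("dialect-%d.yaml", as.integer(year)),
                        package = "esin")
  }
  if (!nzchar(path) || !file.exists(path)) {
    abort(sprintf("unsupported survey year %s: no dialect file available", year))
  }
  d <- yaml::read_yaml(path)
  if (d$year != as.integer(year)) {
    abort(sprintf("dialect file is for year %d, not %s", d$year, year))
  }
  structure(d, class = "esin_dialect")
}

#' Read a raw public-use style visit file
#'
#' Parses a raw visit file (fixed-width ASCII or the raw CSV layout, chosen
#' by the dialect) into the canonical record table: raw names are mapped to
#' canonical fields, sentinel codes become `NA`, implied decimals are
#' applied, checkbox fields become logicals (absent checkbox = `FALSE`),
#' and the year's service indicators are collapsed into the pipe-delimited
#' `services` column. Rows that fail hard invariants (missing/non-positive
#' weight, inconsistent infant age, out-of-range pain) or do not parse are
#' not silently dropped: they are collected into a rejects report attached
#' as `attr(, "rejects")`.
#'
#' @param path Path to the raw file.
#' @param year Survey year, used to pick the shipped dialect.
#' @param dialect Optional `esin_dialect`, overriding `year`.
#' @return Canonical visit tibble with a `rejects` attribute.
#' @export
read_puf <- function(path, year, dialect = NULL) {
  dialect <- dialect %||% load_dialect(year)
  fields <- dialect$fields
  svc <- unlist(dialect$service_fields)
  raw_names <- c(vapply(fields, `[[`, character(1), "raw"), svc)
  if (identical(dialect$format, "fwf") && file.size(path) == 0) {
    out <- validate_records(empty_records())
    return(out)
  }
  if (identical(dialect$format, "fwf")) {
    widths <- c(vapply(fields, function(f) as.integer(f$width), integer(1)),
                rep(2L, length(svc)))
    raw <- readr::read_fwf(
      path, readr::fwf_widths(widths, raw_names),
      col_types = readr::cols(.default = readr::col_character()),
      progress = FALSE
    )
  } else {
    raw <- readr::read_csv(path,
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
    missing_cols <- setdiff(raw_names, names(raw))
    if (length(missing_cols)) {
      weight_raw <- field_for(dialect, "visit_weight")$raw
      if (weight_raw %in% missing_cols) {
        abort(sprintf("raw file lacks required weight column '%s'", weight_raw))
      }
      for (mc in missing_cols) raw[[mc]] <- NA_character_
    }
  }
  weight_raw <- field_for(dialect, "visit_weight")$raw
  if (!weight_raw %in% names(raw)) {
    abort(sprintf("raw file lacks required weight column '%s'", weight_raw))
  }

  n <- nrow(raw)
  out <- list()
  parse_rej <- list()
  for (f in fields) {
    v <- trimws(raw[[f$raw]])
    v[v == ""] <- NA_character_
    sent <- as.character(unlist(f$sentinels))
    if (length(sent)) v[v %in% sent] <- NA_character_
    typ <- f$type %||% "character"
    if (typ %in% c("integer", "numeric")) {
      num <- suppressWarnings(as.numeric(v))
      bad <- !is.na(v) & is.na(num)
      if (any(bad)) {
        parse_rej[[length(parse_rej) + 1L]] <- tibble::tibble(
          row = which(bad), visit_id = NA_character_,
          field = f$canonical, reason = sprintf("unparseable value in %s", f$raw))
      }
      if (!is.null(f$scale)) num <- num * as.numeric(f$scale)
      out[[f$canonical]] <- if (typ == "integer") as.integer(round(num)) else num
    } else if (typ == "checkbox") {
      out[[f$canonical]] <- !is.na(v) & v == "1"
    } else if (typ == "yesno") {
      out[[f$canonical]] <- dplyr::case_match(v, "1" ~ TRUE, "0" ~ FALSE,
                                              .default = NA)
    } else {
      out[[f$canonical]] <- v
    }
  }
  svc_mat <- vapply(svc, function(s) {
    v <- trimws(raw[[s]])
    !is.na(v) & v == "1"
  }, logical(n))
  svc_mat <- matrix(svc_mat, nrow = n,
                    dimnames = list(NULL, svc))
  out$services <- vapply(seq_len(n), function(i) {
    paste(svc[svc_mat[i, ]], collapse = "|")
  }, character(1))
  recs <- coerce_records(tibble::as_tibble(out))

  bad_rows <- if (length(parse_rej)) unique(dplyr::bind_rows(parse_rej)$row) else integer(0)
  parse_rejects <- if (length(parse_rej)) dplyr::bind_rows(parse_rej) else NULL
  if (length(bad_rows)) {
    keep <- setdiff(seq_len(n), bad_rows)
    parse_rejects$visit_id <- recs$visit_id[parse_rejects$row]
    recs <- recs[keep, , drop = FALSE]
  }
  recs <- validate_records(recs)
  rejects <- dplyr::bind_rows(parse_rejects, attr(recs, "rejects"))
  attr(recs, "rejects") <- rejects
  recs
}

field_for <- function(dialect, canonical) {
  for (f in dialect$fields) if (identical(f$canonical, canonical)) return(f)
  NULL
}

#' Write and read visit tables in the project CSV dialect
#'
#' The project CSV dialect is the package's lingua franca: UTF-8, header
#' row, RFC-4180 quoting, canonical column names, empty cells for missing
#' values, `TRUE`/`FALSE` logicals, and pipe-delimited `services`. It
#' round-trips canonical tables losslessly.
#'
#' @param records Canonical visit tibble.
#' @param path File path.
#' @return `read_visits_csv()` returns a validated canonical tibble (with a
#'   `rejects` attribute); writers return `path` invisibly.
#' @export
write_visits_csv <- function(records, path) {
  readr::write_csv(coerce_records(records), path, na = "", progress = FALSE)
  invisible(path)
}

#' @rdname write_visits_csv
#' @export
read_visits_csv <- function(path) {
  raw <- readr::read_csv(path,
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  validate_records(raw)
}

#' Write classified visits to CSV
#'
#' Writes all canonical fields plus `resource_total`, `resource_items`, the
#' pipe-delimited `matched_criteria` audit column and `esin_level`. An empty
#' table produces a header-only CSV. [read_classified_csv()] restores the
#' table losslessly.
#'
#' @param classified Output of [classify_table()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_classified <- function(classified, path) {
  need <- c(esin_fields(), "resource_total", "resource_items",
            "matched_criteria", "esin_level")
  missing_cols <- setdiff(need, names(classified))
  if (length(missing_cols)) {
    abort(sprintf("classified table lacks column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  readr::write_csv(classified[, need], path, na = "", progress = FALSE)
  invisible(path)
}

#' @rdname write_classified
#' @export
read_classified_csv <- function(path) {
  raw <- readr::read_csv(path,
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  recs <- coerce_records(raw)
  recs$resource_total <- as.integer(raw$resource_total)
  recs$resource_items <- ifelse(is.na(raw$resource_items), "", raw$resource_items)
  recs$matched_criteria <- ifelse(is.na(raw$matched_criteria), "", raw$matched_criteria)
  recs$esin_level <- as.integer(raw$esin_level)
  recs
}

#' Write records in a year's raw on-disk convention
#'
#' The inverse of [read_puf()]: canonical records are written back out with
#' the dialect's raw variable names, sentinel codes for missing values,
#' implied decimals and 0/1 indicator fields, so the reader can be
#' integration-tested end-to-end against generated data.
#'
#' @param records Canonical visit tibble.
#' @param dialect An `esin_dialect` (or a year, to use the shipped one).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
emit_raw_files <- function(records, dialect, path) {
  if (is.numeric(dialect)) dialect <- load_dialect(dialect)
  records <- coerce_records(records)
  n <- nrow(records)
  svc <- unlist(dialect$service_fields)
  cols <- list()
  for (f in dialect$fields) {
    v <- records[[f$canonical]]
    sent <- if (length(f$sentinels)) as.character(f$sentinels[[1]]) else ""
    typ <- f$type %||% "character"
    chr <- if (typ %in% c("integer", "numeric")) {
      num <- as.numeric(v)
      if (!is.null(f$scale)) num <- num / as.numeric(f$scale)
      digits <- as.integer(f$digits %||% 0L)
      ifelse(is.na(num), sent, formatC(num, format = "f", digits = digits))
    } else if (typ == "checkbox") {
      ifelse(!is.na(v) & v, "1", "0")
    } else if (typ == "yesno") {
      ifelse(is.na(v), sent, ifelse(v, "1", "0"))
    } else {
      ifelse(is.na(v), "", as.character(v))
    }
    cols[[f$raw]] <- chr
  }
  svc_lists <- split_services(records$services)
  for (s in svc) {
    cols[[s]] <- vapply(seq_len(n), function(i) {
      if (s %in% svc_lists[[i]]) "1" else "0"
    }, character(1))
  }
  if (identical(dialect$format, "fwf")) {
    widths <- c(vapply(dialect$fields, function(f) as.integer(f$width), integer(1)),
                rep(2L, length(svc)))
    lines <- if (n == 0) character(0) else {
      mat <- mapply(function(chr, w) formatC(chr, width = w), cols, widths)
      mat <- matrix(mat, nrow = n)
      apply(mat, 1, paste, collapse = "")
    }
    writeLines(lines, path)
  } else {
    readr::write_csv(tibble::as_tibble(cols), path, na = "", progress = FALSE)
  }
  invisible(path)
}

#' @export
print.esin_dialect <- function(x, ...) {
  cat(sprintf("raw-file dialect for survey year %d (%s): %d fields, %d service indicators\n",
              x$year, x$format, length(x$fields), length(x$service_fields)))
  invisible(x)
}
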