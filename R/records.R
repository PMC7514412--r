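#' Canonical visit-record fields
#'
#' The package represents one ED visit per row in a tibble with a fixed set
#' of canonical columns. Raw survey files (and the project CSV dialect) are
#' normalized into this layout by [read_puf()] / [read_visits_csv()]:
#' sentinel codes become `NA`, implied decimals are applied, and absent
#' checkboxes become `FALSE`.
#'
#' Columns: `visit_id` (character), `year` (integer survey year),
#' `rfv1`--`rfv3` (integer reason-for-visit codes, up to three per visit),
#' `age_years` (completed years), `age_days` (days, only for infants under
#' one year), `pulse_bpm`, `bp_systolic_mmhg`, `temp_f` (one decimal, deg F),
#' `pain_level` (ordinal 0--4), `doa_flag`, `intubation_flag`, `cpr_flag`
#' (logical; dead on arrival, endotracheal intubation, CPR),
#' `services` (pipe-delimited service-item identifiers observed during the
#' visit), `immed_recorded` (recorded five-level immediacy, `0` = no triage,
#' `NA` = unknown), `admitted_flag`, `critical_care_flag`, `ambulance_flag`,
#' `lwbs_flag` (logical outcomes), `wait_minutes`, `los_minutes`,
#' `visit_weight` (positive national inflation weight), `stratum_id`,
#' `psu_id` (masked design variables), `service_area` (optional emergency
#' service area identifier).
#'
#' @return Character vector of canonical column names, in canonical order.
#' @export
#' @examples
#' esin_fields()
esin_fields <- function() {
  c(
    "visit_id", "year", "rfv1", "rfv2", "rfv3",
    "age_years", "age_days",
    "pulse_bpm", "bp_systolic_mmhg", "temp_f", "pain_level",
    "doa_flag", "intubation_flag", "cpr_flag",
    "services", "immed_recorded",
    "admitted_flag", "critical_care_flag", "ambulance_flag", "lwbs_flag",
    "wait_minutes", "los_minutes",
    "visit_weight", "stratum_id", "psu_id", "service_area"
  )
}

# canonical column prototypes, used to build empty tables and coerce types
.field_types <- function() {
  list(
    visit_id = character(), year = integer(),
    rfv1 = integer(), rfv2 = integer(), rfv3 = integer(),
    age_years = integer(), age_days = integer(),
    pulse_bpm = integer(), bp_systolic_mmhg = integer(),
    temp_f = double(), pain_level = integer(),
    doa_flag = logical(), intubation_flag = logical(), cpr_flag = logical(),
    services = character(), immed_recorded = integer(),
    admitted_flag = logical(), critical_care_flag = logical(),
    ambulance_flag = logical(), lwbs_flag = logical(),
    wait_minutes = double(), los_minutes = double(),
    visit_weight = double(), stratum_id = character(), psu_id = character(),
    service_area = character()
  )
}

#' An empty canonical visit table
#'
#' @return Zero-row tibble with all canonical columns and types.
#' @export
empty_records <- function() {
  tibble::as_tibble(.field_types())
}

# effective age in completed years: age_days, when present, is authoritative
# for infants under one year (implies zero completed years)
age_eff_years <- function(records) {
  ifelse(!is.na(records$age_days), 0L, records$age_years)
}

# effective age in days for danger-zone band lookup; completed years are
# converted at 365.25 days/year when no day count is recorded
age_eff_days <- function(records) {
  ifelse(!is.na(records$age_days), as.numeric(records$age_days),
         records$age_years * 365.25)
}

split_services <- function(services) {
  services <- as.character(services)
  services[is.na(services)] <- ""
  out <- strsplit(services, "|", fixed = TRUE)
  lapply(out, function(x) x[nzchar(x)])
}

join_services <- function(items) {
  vapply(items, function(x) paste(x, collapse = "|"), character(1))
}

#' Validate a canonical visit table
#'
#' Checks the hard row invariants of the canonical layout: a positive visit
#' weight, `age_days` only alongside `age_years == 0`, and `pain_level` in
#' 0--4 when present. Violating rows are separated into a rejects report
#' rather than silently dropped.
#'
#' @param records Tibble of canonical visit records.
#' @return The conforming rows, with a `rejects` attribute: a tibble with
#'   columns `row`, `visit_id`, `field`, `reason` (zero rows when all
#'   records conform).
#' @export
validate_records <- function(records) {
  records <- coerce_records(records)
  n <- nrow(records)
  rej <- list()
  bad_weight <- is.na(records$visit_weight) | records$visit_weight <= 0
  if (any(bad_weight)) {
    rej[[length(rej) + 1L]] <- tibble::tibble(
      row = which(bad_weight), visit_id = records$visit_id[bad_weight],
      field = "visit_weight", reason = "missing or non-positive visit weight"
    )
  }
  bad_age <- !is.na(records$age_days) &
    (is.na(records$age_years) | records$age_years != 0L)
  if (any(bad_age)) {
    rej[[length(rej) + 1L]] <- tibble::tibble(
      row = which(bad_age), visit_id = records$visit_id[bad_age],
      field = "age_days", reason = "age_days present but age_years != 0"
    )
  }
  bad_pain <- !is.na(records$pain_level) &
    !(records$pain_level %in% 0:4)
  if (any(bad_pain)) {
    rej[[length(rej) + 1L]] <- tibble::tibble(
      row = which(bad_pain), visit_id = records$visit_id[bad_pain],
      field = "pain_level", reason = "pain_level outside 0-4"
    )
  }
  rejects <- if (length(rej)) dplyr::bind_rows(rej) else
    tibble::tibble(row = integer(), visit_id = character(),
                   field = character(), reason = character())
  keep <- setdiff(seq_len(n), unique(rejects$row))
  out <- records[keep, , drop = FALSE]
  if (nrow(rejects) > 0) {
    inform(sprintf("validate_records: rejected %d of %d rows (see attr(., 'rejects'))",
                   length(unique(rejects$row)), n))
  }
  attr(out, "rejects") <- rejects
  out
}

# coerce a data frame with canonical column names to canonical types,
# adding absent optional columns as all-missing
coerce_records <- function(records) {
  proto <- .field_types()
  # fast path: already canonical (names and types match), only normalize
  # the services item order
  if (is.data.frame(records) && identical(names(records), names(proto)) &&
      identical(unname(vapply(records, function(x) class(x)[1], character(1))),
                unname(vapply(proto, function(x) class(x)[1], character(1))))) {
    return(normalize_services(records))
  }
  records <- tibble::as_tibble(records)
  for (f in names(proto)) {
    if (!f %in% names(records)) {
      records[[f]] <- proto[[f]][NA_integer_][rep(1L, nrow(records))]
      if (f == "services") records[[f]] <- rep("", nrow(records))
      next
    }
    target <- proto[[f]]
    records[[f]] <- switch(class(target)[1],
      character = as.character(records[[f]]),
      integer = as.integer(records[[f]]),
      numeric = as.numeric(records[[f]]),
      logical = as.logical(records[[f]])
    )
  }
  normalize_services(records[, names(proto)])
}

# canonical item order makes the services field order-insensitive and
# raw/CSV round trips exact
normalize_services <- function(records) {
  s <- records$services
  s[is.na(s)] <- ""
  has_items <- nzchar(s)
  if (any(has_items)) {
    s[has_items] <- join_services(lapply(split_services(s[has_items]), sort))
  }
  records$services <- s
  records
}
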