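#' Load and validate an ESI-N criteria configuration
#'
#' The classification rules live entirely in configuration: reason-for-visit
#' (RFV) code sets keyed by verbatim condition labels, resuscitation-flag
#' criteria, the two adult level-1 vital rules, age-banded danger-zone vital
#' thresholds, the severe-pain / pediatric-fever / motor-vehicle-accident
#' rules, and the resource group definitions. The shipped default lives at
#' `system.file("extdata", "criteria.yaml", package = "esin")` (with a JSON
#' mirror alongside). Loading performs a completeness check: every required
#' condition label must appear exactly once, code sets must be nonempty, and
#' danger-zone age bands must be disjoint.
#'
#' @param config_path Path to a YAML (or JSON) criteria file. Defaults to the
#'   shipped configuration.
#' @return An object of class `esin_criteria`.
#' @export
#' @examples
#' cfg <- load_criteria()
#' cfg
load_criteria <- function(config_path = NULL) {
  if (is.null(config_path)) {
    config_path <- system.file("extdata", "criteria.yaml", package = "esin")
  }
  if (!file.exists(config_path)) {
    abort(sprintf("criteria config not found: %s", config_path))
  }
  raw <- if (grepl("\\.json$", config_path, ignore.case = TRUE)) {
    jsonlite::read_json(config_path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(config_path)
  }
  cfg <- structure(raw, class = "esin_criteria")
  validate_criteria(cfg)
  cfg
}

# labels that must each appear exactly once for the catalog to be complete
required_criteria_labels <- function() {
  c(
    "Dead on arrival (RFV code)", "Respiratory arrest", "Cardiac arrest",
    "Cardiopulmonary arrest", "Unconscious on arrival",
    "Dead on arrival (checkbox)", "Pulse \u226450 and age >25",
    "Endotracheal intubation", "Cardiopulmonary resuscitation",
    "Systolic blood pressure \u226480 and Age >25",
    "Fainting (Syncope)", "Hostile behavior",
    "Neurological weakness or speech difficulty",
    "Shortness of breath/breathing problem", "Gastrointestinal bleeding",
    "Retention of urine", "Sepsis, septicemia", "Ischemic heart disease",
    "Violence/self-harm", "Rape", "Altered level of consciousness",
    "Abdominal pain (elderly)", "Abdominal pain, vomiting and diarrhea",
    "Abdominal pain (youth)", "Head Trauma (infants)",
    "Severe pain", "Pediatric fever", "Motor vehicle accident"
  )
}

validate_criteria <- function(cfg) {
  labels <- c(
    vapply(cfg$level1$rfv_conditions, `[[`, character(1), "name"),
    vapply(cfg$level1$flags, `[[`, character(1), "name"),
    vapply(cfg$level1$vitals, `[[`, character(1), "name"),
    vapply(cfg$level2$rfv_conditions, `[[`, character(1), "name"),
    cfg$level3$severe_pain$name,
    cfg$level3$pediatric_fever$name,
    cfg$level3$motor_vehicle_accident$name
  )
  required <- required_criteria_labels()
  missing <- setdiff(required, labels)
  if (length(missing)) {
    abort(sprintf("criteria config incomplete; missing condition row(s): %s",
                  paste(missing, collapse = "; ")))
  }
  dup <- labels[duplicated(labels)]
  if (length(dup)) {
    abort(sprintf("criteria config has duplicated condition row(s): %s",
                  paste(unique(dup), collapse = "; ")))
  }
  for (cond in c(cfg$level1$rfv_conditions, cfg$level2$rfv_conditions)) {
    codes <- unlist(c(cond$codes, cond$all_of))
    if (length(codes) == 0) {
      abort(sprintf("condition '%s' has an empty RFV code set", cond$name))
    }
  }
  bands <- cfg$level2$vital_bands
  if (length(bands) < 1) abort("criteria config has no danger-zone vital bands")
  iv <- t(vapply(bands, band_interval_days, numeric(2)))
  ord <- order(iv[, 1])
  iv <- iv[ord, , drop = FALSE]
  if (any(iv[, 1] >= iv[, 2])) abort("danger-zone age band with empty interval")
  if (nrow(iv) > 1 && any(iv[-1, 1] < iv[-nrow(iv), 2])) {
    abort("danger-zone age bands overlap; bands must be disjoint")
  }
  validate_resource_defs(cfg$resources)
  invisible(cfg)
}

# half-open [min, max) band interval in days; years convert at 365.25
band_interval_days <- function(band) {
  lo <- band$age_min_days %||% (if (!is.null(band$age_min_years)) band$age_min_years * 365.25 else 0)
  hi <- band$age_max_days %||% (if (!is.null(band$age_max_years)) band$age_max_years * 365.25 else Inf)
  c(as.numeric(lo), as.numeric(hi))
}

#' @export
print.esin_criteria <- function(x, ...) {
  n_bands <- length(x$level2$vital_bands)
  cat("ESI-N criteria configuration\n")
  cat(sprintf("  level 1: %d RFV conditions, %d flag criteria, %d vital rules\n",
              length(x$level1$rfv_conditions), length(x$level1$flags),
              length(x$level1$vitals)))
  cat(sprintf("  level 2: %d RFV conditions, %d danger-zone vital bands\n",
              length(x$level2$rfv_conditions), n_bands))
  cat(sprintf("  level 3: severe pain (>= %s), pediatric fever (age < %s y, temp >= %s F), MVA codes (%d)\n",
              x$level3$severe_pain$pain_min, x$level3$pediatric_fever$age_max_years,
              x$level3$pediatric_fever$temp_ge_f,
              length(x$level3$motor_vehicle_accident$codes)))
  cat(sprintf("  resources: %d groups, %d excluded items\n",
              length(x$resources$groups), length(x$resources$excluded_items)))
  invisible(x)
}

#' Serialize a criteria configuration
#'
#' Writes the configuration back out as YAML or JSON (chosen by file
#' extension); reloading the result yields an equivalent configuration.
#'
#' @param cfg An `esin_criteria` object.
#' @param path Output path ending in `.yaml`/`.yml` or `.json`.
#' @return `path`, invisibly.
#' @export
write_criteria <- function(cfg, path) {
  stopifnot(inherits(cfg, "esin_criteria"))
  x <- unclass(cfg)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' Match a reason-for-visit condition against visit records
#'
#' A condition matches when any of the record's up to three RFV codes falls
#' in the condition's code set (for `all_of` conditions, every listed code
#' family must be represented among the three codes) and the record passes
#' the condition's age gate, if any. A record with missing age fails an
#' age-gated condition.
#'
#' @param records Canonical visit tibble.
#' @param code_set One condition entry (a list with `name`, `codes` or
#'   `all_of`, optional `age_min_years` / `age_max_years`).
#' @return Logical vector, one element per record.
#' @export
match_rfv <- function(records, code_set) {
  rfv <- cbind(records$rfv1, records$rfv2, records$rfv3)
  in_set <- function(codes) {
    m <- matrix(rfv %in% unlist(codes), nrow = nrow(records))
    rowSums(m, na.rm = TRUE) > 0
  }
  hit <- if (!is.null(code_set$all_of)) {
    Reduce(`&`, lapply(code_set$all_of, in_set))
  } else {
    in_set(code_set$codes)
  }
  age <- age_eff_years(records)
  if (!is.null(code_set$age_min_years)) {
    hit <- hit & !is.na(age) & age >= code_set$age_min_years
  }
  if (!is.null(code_set$age_max_years)) {
    hit <- hit & !is.na(age) & age < code_set$age_max_years
  }
  hit
}

#' Danger-zone vital-sign check
#'
#' True for a record when its age selects one of the configured age bands
#' and a *present* vital sign crosses that band's threshold (pulse strictly
#' above `pulse_gt`, or temperature at or above `temp_ge_f`). Missing vitals
#' never fire the criterion: the classification is left unchanged rather
#' than missing.
#'
#' @param records Canonical visit tibble.
#' @param bands List of band entries (from an `esin_criteria` object).
#' @return Logical vector, one element per record.
#' @export
danger_zone_vitals <- function(records, bands) {
  days <- age_eff_days(records)
  out <- rep(FALSE, nrow(records))
  for (band in bands) {
    iv <- band_interval_days(band)
    in_band <- !is.na(days) & days >= iv[1] & days < iv[2]
    fire <- rep(FALSE, nrow(records))
    if (!is.null(band$pulse_gt)) {
      fire <- fire | (!is.na(records$pulse_bpm) & records$pulse_bpm > band$pulse_gt)
    }
    if (!is.null(band$temp_ge_f)) {
      fire <- fire | (!is.na(records$temp_f) & records$temp_f >= band$temp_ge_f)
    }
    out <- out | (in_band & fire)
  }
  out
}
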