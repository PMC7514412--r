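#' Classify visits into ESI-N levels
#'
#' Assigns each visit exactly one severity/complexity level 1--5 by the
#' stepwise procedure the index is built on:
#' \enumerate{
#'   \item \strong{Level 1 (Immediate)}: a level-1 reason-for-visit code
#'     (cardiac/respiratory/cardiopulmonary arrest, unconscious or dead on
#'     arrival), a resuscitation flag (DOA checkbox, endotracheal
#'     intubation, CPR), or an adult vital extreme (pulse at or below 50, or
#'     systolic blood pressure at or below 80, with age over 25).
#'   \item \strong{Level 2 (Emergent)}, if not level 1: a level-2
#'     reason-for-visit condition (some age-gated), or a danger-zone
#'     vital sign for the patient's age band.
#'   \item \strong{Level 3 (Urgent)}, if not level 1--2: more than one
#'     resource used, severe pain, pediatric fever, or a motor-vehicle
#'     accident.
#'   \item \strong{Level 4 (Semi-urgent)}: exactly one resource used.
#'   \item \strong{Level 5 (Nonurgent)}: no resource used.
#' }
#' Missing fields never fire a criterion, so every normalized record gets a
#' level: a visit with everything missing falls through to level 5.
#' The classification keys on the presenting complaint (RFV codes), not the
#' final diagnosis, and tallies resources actually used, not predicted.
#'
#' `classify_table()` is the vectorized production path; `assign_level()`
#' classifies a single record; `oracle_assign_level()` is an intentionally
#' independent scalar re-evaluation of every criterion with no early exit,
#' kept solely to cross-check the production path.
#'
#' @param records Canonical visit tibble (see [esin_fields()]).
#' @param config An `esin_criteria` object from [load_criteria()].
#' @param unknown_items Passed to [count_resources()].
#' @return `classify_table()`: the input tibble plus `esin_level` (integer
#'   1--5), `resource_total`, `resource_items`, and `matched_criteria`, a
#'   pipe-delimited audit trail of every criterion that fired, as
#'   `level:label` entries ordered by level.
#' @export
#' @examples
#' cfg <- load_criteria()
#' recs <- coerce_records_public(tibble::tibble(
#'   visit_id = c("a", "b"), age_years = c(30L, 30L),
#'   pulse_bpm = c(45L, NA), services = c("", "CBC|XRAY"),
#'   visit_weight = c(1, 1)
#' ))
#' classify_table(recs, cfg)[, c("visit_id", "esin_level", "matched_criteria")]
classify_table <- function(records, config, unknown_items = c("warn", "strict")) {
  stopifnot(inherits(config, "esin_criteria"))
  records <- coerce_records(records)
  n <- nrow(records)
  res <- count_resources(records, config$resources, unknown_items)
  if (n == 0) {
    out <- dplyr::bind_cols(records, res)
    out$matched_criteria <- character(0)
    out$esin_level <- integer(0)
    return(out)
  }

  fired <- list()  # each: list(level, label, hit = logical vector)
  add <- function(level, label, hit) {
    fired[[length(fired) + 1L]] <<- list(level = level, label = label, hit = hit)
  }

  age <- age_eff_years(records)
  for (cond in config$level1$rfv_conditions) {
    add(1L, cond$name, match_rfv(records, cond))
  }
  for (fl in config$level1$flags) {
    v <- records[[fl$field]]
    add(1L, fl$name, !is.na(v) & v)
  }
  for (vr in config$level1$vitals) {
    v <- records[[vr$vital]]
    add(1L, vr$name,
        !is.na(v) & v <= vr$le & !is.na(age) & age > vr$age_gt_years)
  }
  for (cond in config$level2$rfv_conditions) {
    add(2L, cond$name, match_rfv(records, cond))
  }
  add(2L, "Level 3 exceeding vital sign thresholds",
      danger_zone_vitals(records, config$level2$vital_bands))
  sp <- config$level3$severe_pain
  add(3L, sp$name, !is.na(records$pain_level) & records$pain_level >= sp$pain_min)
  pf <- config$level3$pediatric_fever
  add(3L, pf$name,
      !is.na(age) & age < pf$age_max_years &
        !is.na(records$temp_f) & records$temp_f >= pf$temp_ge_f)
  mva <- config$level3$motor_vehicle_accident
  add(3L, mva$name, match_rfv(records, mva))
  # resource partition: exactly one of these fires on every record, so the
  # fall-through levels 3/4/5 are total
  add(3L, "More than 1 resource used", res$resource_total > 1L)
  add(4L, "One resource used", res$resource_total == 1L)
  add(5L, "No resource used", res$resource_total == 0L)

  level <- rep(5L, n)
  matched <- rep("", n)
  ord <- order(vapply(fired, `[[`, integer(1), "level"))
  for (f in fired[ord]) {
    level <- pmin(level, ifelse(f$hit, f$level, 5L))
    piece <- paste0(f$level, ":", f$label)
    matched <- ifelse(f$hit,
                      ifelse(nzchar(matched), paste(matched, piece, sep = "|"), piece),
                      matched)
  }
  out <- dplyr::bind_cols(records, res)
  out$matched_criteria <- matched
  out$esin_level <- level
  tally <- table(factor(level, levels = 1:5))
  inform(sprintf("classified %d visits; unweighted level tallies 1-5: %s",
                 n, paste(as.integer(tally), collapse = ", ")))
  out
}

#' @rdname classify_table
#' @param record A single canonical record (1-row tibble).
#' @return `assign_level()`: a 1-row classified tibble.
#' @export
assign_level <- function(record, config, unknown_items = c("warn", "strict")) {
  record <- coerce_records(record)
  if (nrow(record) != 1L) abort("assign_level expects exactly one record")
  withCallingHandlers(
    classify_table(record, config, unknown_items),
    message = function(m) invokeRestart("muffleMessage")
  )
}

#' @rdname classify_table
#' @details `oracle_assign_level()` shares no evaluation code with
#'   `classify_table()`: it walks the configuration with plain scalar loops,
#'   evaluates every criterion, and returns the minimum level among those
#'   that fired (the resource tally supplying the 3/4/5 fall-through). It is
#'   deliberately slow and simple.
#' @return `oracle_assign_level()`: a single integer level.
#' @export
oracle_assign_level <- function(record, config) {
  record <- coerce_records(record)
  if (nrow(record) != 1L) abort("oracle_assign_level expects exactly one record")
  rfv <- c(record$rfv1, record$rfv2, record$rfv3)
  rfv <- rfv[!is.na(rfv)]
  age <- if (!is.na(record$age_days)) 0L else record$age_years
  days <- if (!is.na(record$age_days)) as.numeric(record$age_days) else
    if (!is.na(record$age_years)) record$age_years * 365.25 else NA_real_

  match_cond <- function(cond) {
    ok <- if (!is.null(cond$all_of)) {
      all(vapply(cond$all_of, function(g) any(rfv %in% unlist(g)), logical(1)))
    } else {
      any(rfv %in% unlist(cond$codes))
    }
    if (!ok) return(FALSE)
    if (!is.null(cond$age_min_years)) {
      if (is.na(age) || age < cond$age_min_years) return(FALSE)
    }
    if (!is.null(cond$age_max_years)) {
      if (is.na(age) || age >= cond$age_max_years) return(FALSE)
    }
    TRUE
  }

  levels_hit <- integer(0)
  for (cond in config$level1$rfv_conditions) {
    if (match_cond(cond)) levels_hit <- c(levels_hit, 1L)
  }
  for (fl in config$level1$flags) {
    v <- record[[fl$field]]
    if (!is.na(v) && isTRUE(v)) levels_hit <- c(levels_hit, 1L)
  }
  for (vr in config$level1$vitals) {
    v <- record[[vr$vital]]
    if (!is.na(v) && v <= vr$le && !is.na(age) && age > vr$age_gt_years) {
      levels_hit <- c(levels_hit, 1L)
    }
  }
  for (cond in config$level2$rfv_conditions) {
    if (match_cond(cond)) levels_hit <- c(levels_hit, 2L)
  }
  for (band in config$level2$vital_bands) {
    iv <- band_interval_days(band)
    if (!is.na(days) && days >= iv[1] && days < iv[2]) {
      p <- record$pulse_bpm
      t <- record$temp_f
      if (!is.null(band$pulse_gt) && !is.na(p) && p > band$pulse_gt) {
        levels_hit <- c(levels_hit, 2L)
      }
      if (!is.null(band$temp_ge_f) && !is.na(t) && t >= band$temp_ge_f) {
        levels_hit <- c(levels_hit, 2L)
      }
    }
  }
  sp <- config$level3$severe_pain
  if (!is.na(record$pain_level) && record$pain_level >= sp$pain_min) {
    levels_hit <- c(levels_hit, 3L)
  }
  pf <- config$level3$pediatric_fever
  if (!is.na(age) && age < pf$age_max_years &&
      !is.na(record$temp_f) && record$temp_f >= pf$temp_ge_f) {
    levels_hit <- c(levels_hit, 3L)
  }
  if (match_cond(config$level3$motor_vehicle_accident)) {
    levels_hit <- c(levels_hit, 3L)
  }

  # independent resource tally: walk the groups by hand
  items <- strsplit(ifelse(is.na(record$services), "", record$services),
                    "|", fixed = TRUE)[[1]]
  items <- setdiff(items[nzchar(items)], unlist(config$resources$excluded_items))
  total <- 0L
  for (grp in config$resources$groups) {
    if (any(items %in% unlist(grp$items))) total <- total + as.integer(grp$count)
  }
  levels_hit <- c(levels_hit,
                  if (total > 1L) 3L else if (total == 1L) 4L else 5L)
  min(levels_hit)
}
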