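# build a 1-or-more-row canonical record table from overrides; everything
# else is missing except a unit weight
make_records <- function(...) {
  over <- list(...)
  n <- if (length(over)) max(lengths(over)) else 1L
  base <- list(visit_id = sprintf("T%03d", seq_len(n)), visit_weight = rep(1, n))
  base[names(over)] <- over
  coerce_records_public(tibble::as_tibble(base))
}

quiet_classify <- function(records, cfg, ...) {
  suppressMessages(suppressWarnings(classify_table(records, cfg, ...)))
}

# adversarial record fuzzer: arbitrary combinations of configured codes,
# ages (including missing), extreme vitals, flags and service items
random_records <- function(n, cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  all_codes <- unique(unlist(c(
    lapply(cfg$level1$rfv_conditions, function(x) c(x$codes, x$all_of)),
    lapply(cfg$level2$rfv_conditions, function(x) c(x$codes, x$all_of)),
    cfg$level3$motor_vehicle_accident$codes
  )))
  code_pool <- c(all_codes, 20050L, 26050L, 30000L, NA_integer_)
  items <- unlist(lapply(cfg$resources$groups, `[[`, "items"))
  items <- c(items, unlist(cfg$resources$excluded_items))
  pick_codes <- function() sample(code_pool, 3, replace = TRUE)
  rfv <- t(replicate(n, pick_codes()))
  age_years <- sample(c(NA_integer_, 0:95), n, replace = TRUE)
  age_days <- ifelse(!is.na(age_years) & age_years == 0L &
                       runif(n) < 0.7,
                     sample(0:364, n, replace = TRUE), NA_integer_)
  svc <- vapply(seq_len(n), function(i) {
    k <- sample(0:5, 1)
    paste(sample(items, k), collapse = "|")
  }, character(1))
  make_records(
    visit_id = sprintf("F%06d", seq_len(n)),
    rfv1 = rfv[, 1], rfv2 = rfv[, 2], rfv3 = rfv[, 3],
    age_years = age_years, age_days = age_days,
    pulse_bpm = sample(c(NA_integer_, 20:220), n, replace = TRUE),
    bp_systolic_mmhg = sample(c(NA_integer_, 50:200), n, replace = TRUE),
    temp_f = round(runif(n, 95, 105), 1),
    pain_level = sample(c(NA_integer_, 0:4), n, replace = TRUE),
    doa_flag = runif(n) < 0.02, intubation_flag = runif(n) < 0.02,
    cpr_flag = runif(n) < 0.02,
    services = svc,
    immed_recorded = sample(c(NA_integer_, 0:5), n, replace = TRUE),
    visit_weight = rep(1, n)
  )
}
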