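#' Specify a synthetic visit mixture
#'
#' Configuration for the synthetic-record generator. Defaults encode the
#' study conditions the package's estimators are exercised under: the
#' five-level mixture follows the weighted level shares the index produces
#' on the pooled 2010--2015 survey (1.4 / 24.5 / 42.5 / 15.1 / 16.4
#' percent), per-level admission, critical-care, ambulance and
#' left-without-being-seen probabilities and mean waiting/boarding times
#' follow the published outcome-by-level tables, and 15 percent of visits
#' have unknown or not-performed triage immediacy. Visit weights are
#' log-normal to mimic right-skewed national inflation weights; the
#' parameters are configuration, not an assertion about the survey.
#'
#' @param n Number of records.
#' @param level_probs Length-5 probability vector for planted levels; must
#'   sum to 1 (vectors within 0.005 of 1, e.g. printed rounded shares, are
#'   renormalized).
#' @param vital_missing_rate,pain_missing_rate Probability that each vital
#'   sign (pulse, systolic BP, temperature), or the pain score, is blanked
#'   on records where it is not load-bearing for the planted criterion.
#' @param weight_meanlog,weight_sdlog Log-normal visit-weight parameters.
#' @param strata,psus_per_stratum Masked design structure.
#' @param outcome_model List with per-level probability vectors `admit`,
#'   `icu`, `ambulance`, `lwbs` and per-level duration means `wait_mean`,
#'   `los_mean` (minutes; log-normal with `duration_sdlog`).
#' @param immed_unknown_rate Share of visits with unknown/no-triage
#'   immediacy.
#' @param immed_agreement Probability that known recorded immediacy equals
#'   the planted level (otherwise one level off).
#' @param seed Integer seed; identical seeds give identical tables.
#' @return A list of class `esin_mixture`.
#' @export
mixture_spec <- function(n = 10000,
                         level_probs = c(0.014, 0.245, 0.425, 0.151, 0.164),
                         vital_missing_rate = 0.10,
                         pain_missing_rate = 0.10,
                         weight_meanlog = log(250), weight_sdlog = 0.6,
                         strata = 8L, psus_per_stratum = 4L,
                         outcome_model = default_outcome_model(),
                         immed_unknown_rate = 0.15,
                         immed_agreement = 0.7,
                         seed = NULL) {
  spec <- structure(
    list(n = as.integer(n), level_probs = level_probs,
         vital_missing_rate = vital_missing_rate,
         pain_missing_rate = pain_missing_rate,
         weight_meanlog = weight_meanlog, weight_sdlog = weight_sdlog,
         strata = as.integer(strata),
         psus_per_stratum = as.integer(psus_per_stratum),
         outcome_model = outcome_model,
         immed_unknown_rate = immed_unknown_rate,
         immed_agreement = immed_agreement,
         seed = seed),
    class = "esin_mixture"
  )
  validate_mixture(spec)
}

#' @rdname mixture_spec
#' @export
default_outcome_model <- function() {
  list(
    admit = c(0.379, 0.180, 0.123, 0.025, 0.015),
    icu = c(0.145, 0.026, 0.011, 0.002, 0.001),
    ambulance = c(0.542, 0.205, 0.172, 0.082, 0.051),
    lwbs = c(0.001, 0.012, 0.010, 0.006, 0.012),
    wait_mean = c(13.5, 22.5, 24.4, 24.5, 24.9),
    los_mean = c(201.4, 180.2, 182.7, 119.5, 82.9),
    duration_sdlog = 0.7
  )
}

validate_mixture <- function(spec) {
  p <- spec$level_probs
  if (length(p) != 5 || any(is.na(p)) || any(p < 0) || any(p > 1)) {
    abort("level_probs must be 5 probabilities in [0, 1]")
  }
  s <- sum(p)
  if (abs(s - 1) > 0.005) {
    abort(sprintf("level_probs sum to %.4f; must sum to 1", s))
  }
  spec$level_probs <- p / s
  if (spec$n < 0) abort("n must be >= 0")
  rates <- c(spec$vital_missing_rate, spec$pain_missing_rate,
             spec$immed_unknown_rate, spec$immed_agreement,
             unlist(spec$outcome_model[c("admit", "icu", "ambulance", "lwbs")]))
  if (any(rates < 0 | rates > 1)) abort("all probabilities must lie in [0, 1]")
  spec
}

#' @rdname mixture_spec
#' @param path Path to a YAML mixture file with any of the `mixture_spec()`
#'   arguments as keys.
#' @export
read_mixture_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$outcome_model)) {
    om <- default_outcome_model()
    om[names(raw$outcome_model)] <- raw$outcome_model
    raw$outcome_model <- om
  }
  do.call(mixture_spec, raw)
}

#' Generate synthetic visit records with planted ESI-N levels
#'
#' Draws a planted level for each record from the mixture and constructs a
#' record that fires exactly one criterion of that level -- drawn uniformly
#' from the level's criterion menu -- and, by construction, no more-acute
#' criterion: reason-for-visit codes come only from the planted condition's
#' code set (otherwise from a benign pool outside every configured set) and
#' vitals are clamped into the safe region of every non-planted rule.
#' Resource counts are planted consistently (level 3 by resources gets two
#' or more; level 4 exactly one; level 5 none). Design fields, log-normal
#' weights, recorded immediacy and per-level outcomes are filled in from
#' the spec. The classifier therefore reproduces the planted label on every
#' record; this is the generator's core contract, asserted in the tests.
#'
#' @param spec An `esin_mixture` from [mixture_spec()].
#' @param config Criteria configuration the plants are drawn from.
#' @return List with `records` (canonical tibble) and `labels` (integer
#'   vector of planted levels).
#' @export
generate_records <- function(spec = mixture_spec(), config = load_criteria()) {
  spec <- validate_mixture(spec)
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$n
  if (n == 0) {
    return(list(records = empty_records(), labels = integer(0)))
  }
  labels <- sample(1:5, n, replace = TRUE, prob = spec$level_probs)

  benign_rfv <- c(20050L, 26050L, 30000L)  # outside every configured code set
  pick1 <- function(v) v[[sample.int(length(v), 1L)]]  # never the 1:x shortcut
  simple_groups <- Filter(function(g) as.integer(g$count) == 1, config$resources$groups)
  pick_items <- function(k) {
    grps <- sample(simple_groups, k)
    vapply(grps, function(g) pick1(unlist(g$items)), character(1))
  }

  rec <- list(
    visit_id = sprintf("V%07d", seq_len(n)),
    year = sample(2010:2015, n, replace = TRUE),
    rfv1 = sample(benign_rfv, n, replace = TRUE),
    rfv2 = rep(NA_integer_, n), rfv3 = rep(NA_integer_, n),
    age_years = sample(26:60, n, replace = TRUE),
    age_days = rep(NA_integer_, n),
    pulse_bpm = sample(60:95, n, replace = TRUE),
    bp_systolic_mmhg = sample(100:140, n, replace = TRUE),
    temp_f = round(runif(n, 97.0, 99.0), 1),
    pain_level = sample(0:3, n, replace = TRUE),
    doa_flag = rep(FALSE, n), intubation_flag = rep(FALSE, n),
    cpr_flag = rep(FALSE, n),
    services = rep("", n)
  )
  keep_vital <- matrix(FALSE, n, 3,
                       dimnames = list(NULL, c("pulse", "bp", "temp")))
  keep_pain <- rep(FALSE, n)

  l1_menu <- c(lapply(config$level1$rfv_conditions, function(x) list(kind = "rfv", cond = x)),
               lapply(config$level1$flags, function(x) list(kind = "flag", cond = x)),
               lapply(config$level1$vitals, function(x) list(kind = "vital", cond = x)))
  l2_menu <- c(lapply(config$level2$rfv_conditions, function(x) list(kind = "rfv", cond = x)),
               lapply(seq_along(config$level2$vital_bands),
                      function(i) list(kind = "band", band = config$level2$vital_bands[[i]], idx = i)))
  l3_menu <- list(list(kind = "resources"), list(kind = "pain"),
                  list(kind = "fever"), list(kind = "mva"))

  plant_rfv <- function(i, cond) {
    slot <- sample(1:3, 1)
    if (!is.null(cond$all_of)) {
      codes <- vapply(cond$all_of, function(g) as.integer(pick1(unlist(g))), integer(1))
      rec$rfv1[i] <<- codes[1]; rec$rfv2[i] <<- codes[2]; rec$rfv3[i] <<- codes[3]
    } else {
      code <- as.integer(pick1(unlist(cond$codes)))
      if (slot == 1) rec$rfv1[i] <<- code
      else if (slot == 2) rec$rfv2[i] <<- code
      else rec$rfv3[i] <<- code
    }
    if (!is.null(cond$age_min_years)) {
      rec$age_years[i] <<- sample(cond$age_min_years:(cond$age_min_years + 25), 1)
    }
    if (!is.null(cond$age_max_years)) {
      if (cond$age_max_years <= 1) {
        rec$age_years[i] <<- 0L
        rec$age_days[i] <<- sample(95:360, 1)  # past the young-infant band
      } else {
        rec$age_years[i] <<- 1L
      }
    }
  }

  for (i in seq_len(n)) {
    L <- labels[i]
    if (L == 1L) {
      m <- sample(l1_menu, 1)[[1]]
      if (m$kind == "rfv") plant_rfv(i, m$cond)
      else if (m$kind == "flag") rec[[m$cond$field]][i] <- TRUE
      else {
        if (m$cond$vital == "pulse_bpm") {
          rec$pulse_bpm[i] <- sample(30:50, 1); keep_vital[i, "pulse"] <- TRUE
        } else {
          rec$bp_systolic_mmhg[i] <- sample(60:80, 1); keep_vital[i, "bp"] <- TRUE
        }
      }
      rec$services[i] <- paste(pick_items(sample(0:3, 1)), collapse = "|")
    } else if (L == 2L) {
      m <- sample(l2_menu, 1)[[1]]
      if (m$kind == "rfv") plant_rfv(i, m$cond)
      else {
        iv <- band_interval_days(m$band)
        if (iv[2] <= 90) {               # young-infant band
          rec$age_years[i] <- 0L
          rec$age_days[i] <- sample(0:89, 1)
        } else if (iv[1] < 365) {        # to age 3: plant at age 1-2
          rec$age_years[i] <- sample(1:2, 1)
        } else if (iv[2] < Inf) {        # 3 to 8
          rec$age_years[i] <- sample(3:7, 1)
        } else {                         # adult band
          rec$age_years[i] <- sample(26:60, 1)
        }
        if (!is.null(m$band$pulse_gt) &&
            (is.null(m$band$temp_ge_f) || runif(1) < 0.5)) {
          rec$pulse_bpm[i] <- m$band$pulse_gt + sample(1:30, 1)
          keep_vital[i, "pulse"] <- TRUE
        } else {
          rec$temp_f[i] <- round(m$band$temp_ge_f + runif(1, 0, 2.5), 1)
          keep_vital[i, "temp"] <- TRUE
        }
      }
      rec$services[i] <- paste(pick_items(sample(0:3, 1)), collapse = "|")
    } else if (L == 3L) {
      m <- sample(l3_menu, 1)[[1]]
      if (m$kind == "resources") {
        rec$services[i] <- paste(pick_items(sample(2:4, 1)), collapse = "|")
      } else if (m$kind == "pain") {
        rec$pain_level[i] <- 4L
        keep_pain[i] <- TRUE
        rec$services[i] <- paste(pick_items(sample(0:3, 1)), collapse = "|")
      } else if (m$kind == "fever") {
        pf <- config$level3$pediatric_fever
        rec$age_years[i] <- 1L
        rec$temp_f[i] <- round(pf$temp_ge_f + runif(1, 0, 2.5), 1)
        keep_vital[i, "temp"] <- TRUE
        rec$services[i] <- paste(pick_items(sample(0:3, 1)), collapse = "|")
      } else {
        plant_rfv(i, config$level3$motor_vehicle_accident)
        rec$services[i] <- paste(pick_items(sample(0:3, 1)), collapse = "|")
      }
    } else if (L == 4L) {
      rec$services[i] <- pick_items(1)
    }                                    # level 5: no services
  }

  blank <- function(v, keep, rate) {
    hit <- runif(n) < rate & !keep
    v[hit] <- NA
    v
  }
  rec$pulse_bpm <- blank(rec$pulse_bpm, keep_vital[, "pulse"], spec$vital_missing_rate)
  rec$bp_systolic_mmhg <- blank(rec$bp_systolic_mmhg, keep_vital[, "bp"], spec$vital_missing_rate)
  rec$temp_f <- blank(rec$temp_f, keep_vital[, "temp"], spec$vital_missing_rate)
  rec$pain_level <- blank(rec$pain_level, keep_pain, spec$pain_missing_rate)

  om <- spec$outcome_model
  sdl <- om$duration_sdlog
  rln_mean <- function(m) rlnorm(n, meanlog = log(m) - sdl^2 / 2, sdlog = sdl)
  # ICU admissions are nested within hospital admissions so both per-level
  # marginal rates hold exactly
  rec$admitted_flag <- runif(n) < om$admit[labels]
  p_icu_given_adm <- pmin(1, om$icu[labels] / pmax(om$admit[labels], 1e-12))
  rec$critical_care_flag <- rec$admitted_flag & (runif(n) < p_icu_given_adm)
  rec$ambulance_flag <- runif(n) < om$ambulance[labels]
  rec$lwbs_flag <- runif(n) < om$lwbs[labels]
  rec$wait_minutes <- pmax(1, round(rln_mean(om$wait_mean[labels])))
  rec$los_minutes <- pmax(5, round(rln_mean(om$los_mean[labels])))

  unknown <- runif(n) < spec$immed_unknown_rate
  agree <- runif(n) < spec$immed_agreement
  noisy <- pmin(5L, pmax(1L, labels + sample(c(-1L, 1L), n, replace = TRUE)))
  immed <- ifelse(agree, labels, noisy)
  immed[unknown] <- ifelse(runif(sum(unknown)) < 0.5, NA_integer_, 0L)
  rec$immed_recorded <- as.integer(immed)

  rec$visit_weight <- round(rlnorm(n, spec$weight_meanlog, spec$weight_sdlog), 2)
  stratum <- sample(seq_len(spec$strata), n, replace = TRUE)
  psu <- sample(seq_len(spec$psus_per_stratum), n, replace = TRUE)
  rec$stratum_id <- sprintf("S%02d", stratum)
  rec$psu_id <- sprintf("S%02dP%02d", stratum, psu)
  rec$service_area <- sprintf("A%02d_%02d", stratum, psu)

  records <- coerce_records(tibble::as_tibble(rec))
  list(records = records, labels = labels)
}

#' @export
print.esin_mixture <- function(x, ...) {
  cat(sprintf("synthetic visit mixture: n=%d, level probs (1-5): %s\n",
              x$n, paste(format(x$level_probs, digits = 3), collapse = ", ")))
  invisible(x)
}
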