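#' Describe the survey design of a visit table
#'
#' All national estimates are weighted by the per-visit inflation weight.
#' Variance is estimated either by design-based Taylor linearization over
#' the masked stratum/PSU identifiers (with-replacement first-stage
#' approximation, the standard treatment for public-use survey files) or by
#' a simple-random-sampling fallback that treats each record as its own
#' PSU. Taylor linearization needs at least two PSUs in every stratum; when
#' that fails the estimators degrade to the SRS fallback with a warning.
#'
#' @param weight_field,stratum_field,psu_field Canonical field names.
#' @param variance_method `"taylor"` (default) or `"srs"`.
#' @return A list of class `esin_design`.
#' @export
survey_design <- function(weight_field = "visit_weight",
                          stratum_field = "stratum_id",
                          psu_field = "psu_id",
                          variance_method = c("taylor", "srs")) {
  structure(
    list(weight_field = weight_field, stratum_field = stratum_field,
         psu_field = psu_field, variance_method = match.arg(variance_method)),
    class = "esin_design"
  )
}

#' @export
print.esin_design <- function(x, ...) {
  cat(sprintf("survey design: weight=%s, stratum=%s, psu=%s, variance=%s\n",
              x$weight_field, x$stratum_field, x$psu_field, x$variance_method))
  invisible(x)
}

# resolve design columns against a table; missing stratum/psu forces srs
design_frame <- function(data, design) {
  w <- data[[design$weight_field]]
  if (is.null(w) || all(is.na(w))) abort("all visit weights are missing")
  strata <- data[[design$stratum_field]]
  psu <- data[[design$psu_field]]
  method <- design$variance_method
  if (method == "taylor") {
    if (is.null(strata) || is.null(psu) || all(is.na(strata)) || all(is.na(psu))) {
      warn("design variables unavailable; falling back to SRS variance")
      method <- "srs"
    } else {
      npsu <- tapply(psu, strata, function(p) length(unique(p)))
      if (any(npsu < 2)) {
        warn("stratum with a single PSU; falling back to SRS variance")
        method <- "srs"
      }
    }
  }
  if (method == "srs") {
    strata <- rep("_all", length(w))
    psu <- as.character(seq_along(w))
  }
  list(w = w, strata = as.character(strata), psu = as.character(psu),
       method = method)
}

# variance of a total of linearized scores u_i: sum over strata of
# n_h/(n_h-1) * sum_j (z_hj - zbar_h)^2, z_hj the PSU totals of u
taylor_var <- function(u, strata, psu) {
  key <- paste(strata, psu, sep = "\r")
  z <- tapply(u, key, sum)
  zh <- tapply(u, strata, sum)            # stratum totals (for means)
  hs <- sub("\r.*", "", names(z))
  v <- 0
  for (h in unique(hs)) {
    zj <- z[hs == h]
    nh <- length(zj)
    if (nh < 2) next  # single-PSU stratum contributes no variance
    v <- v + nh / (nh - 1) * sum((zj - mean(zj))^2)
  }
  v
}

# domain (subpopulation) ratio mean and linearized SE; domain defaults to all
svy_mean <- function(x, df, domain = NULL) {
  d <- if (is.null(domain)) rep(TRUE, length(x)) else (domain & !is.na(domain))
  d <- d & !is.na(x) & !is.na(df$w)
  Wd <- sum(df$w[d])
  n <- sum(d)
  if (n == 0 || Wd <= 0) {
    return(list(value = NA_real_, se = NA_real_, n = 0L))
  }
  R <- sum(df$w[d] * x[d]) / Wd
  u <- rep(0, length(x))
  u[d] <- df$w[d] * (x[d] - R) / Wd
  list(value = R, se = sqrt(taylor_var(u, df$strata, df$psu)), n = as.integer(n))
}

svy_total <- function(x, df, domain = NULL) {
  d <- if (is.null(domain)) rep(TRUE, length(x)) else (domain & !is.na(domain))
  d <- d & !is.na(x) & !is.na(df$w)
  u <- rep(0, length(x))
  u[d] <- df$w[d] * x[d]
  list(value = sum(u), se = sqrt(taylor_var(u, df$strata, df$psu)),
       n = as.integer(sum(d)))
}

# symmetric normal-approximation 95% interval; reliability per the
# unweighted n >= 30 rule
wrap_estimate <- function(statistic, est, scale = 1) {
  z <- qnorm(0.975)
  v <- est$value * scale
  se <- est$se * scale
  tibble::tibble(
    statistic = statistic, value = v,
    ci_low = v - z * se, ci_high = v + z * se,
    se = se, unweighted_n = est$n, reliable = est$n >= 30L
  )
}

#' Weighted share of visits at each ESI-N level
#'
#' Survey-weighted percent of visits at each level 1--5, with 95% CIs,
#' unweighted counts and the reliability flag (estimates from fewer than 30
#' unweighted records are flagged unreliable). Shares sum to 100 up to
#' rounding.
#'
#' @param classified Output of [classify_table()].
#' @param design An `esin_design` (default: [survey_design()]).
#' @return Tibble with one row per level: `level`, `statistic`
#'   (`"proportion"`), `value` (percent), `ci_low`, `ci_high`, `se`,
#'   `unweighted_n`, `reliable`.
#' @export
weighted_share_by_level <- function(classified, design = survey_design()) {
  if (nrow(classified) == 0) abort("empty classified table")
  df <- design_frame(classified, design)
  out <- lapply(1:5, function(l) {
    est <- svy_mean(as.numeric(classified$esin_level == l), df)
    est$n <- sum(classified$esin_level == l)  # n at the level, per table convention
    row <- wrap_estimate("proportion", est, scale = 100)
    row$level <- l
    row
  })
  dplyr::bind_rows(out)[, c("level", "statistic", "value", "ci_low", "ci_high",
                            "se", "unweighted_n", "reliable")]
}

#' Weighted mean ESI-N level by group
#'
#' Survey-weighted mean of the integer level within each category of a
#' grouping field (domain estimation over the full design), with 95% CIs
#' and reliability flags.
#'
#' @param classified Output of [classify_table()].
#' @param group_field Canonical field name to group by; `NULL` gives the
#'   overall mean as a single `"all"` row.
#' @param design An `esin_design`.
#' @return Tibble with `group`, `statistic` (`"mean"`), `value`, `ci_low`,
#'   `ci_high`, `se`, `unweighted_n`, `reliable`, `weighted_total`.
#' @export
mean_level_by_group <- function(classified, group_field = NULL,
                                design = survey_design()) {
  df <- design_frame(classified, design)
  g <- if (is.null(group_field)) rep("all", nrow(classified)) else {
    if (!group_field %in% names(classified)) {
      abort(sprintf("unknown grouping field '%s'", group_field))
    }
    v <- as.character(classified[[group_field]])
    ifelse(is.na(v), "(missing)", v)
  }
  out <- lapply(sort(unique(g)), function(grp) {
    dom <- g == grp
    est <- svy_mean(as.numeric(classified$esin_level), df, domain = dom)
    row <- wrap_estimate("mean", est)
    row$group <- grp
    row$weighted_total <- sum(df$w[dom & !is.na(df$w)])
    row
  })
  dplyr::bind_rows(out)[, c("group", "statistic", "value", "ci_low", "ci_high",
                            "se", "unweighted_n", "reliable", "weighted_total")]
}

outcome_columns <- function() {
  c(admitted = "admitted_flag", critical_care = "critical_care_flag",
    ambulance = "ambulance_flag", lwbs = "lwbs_flag",
    wait_minutes = "wait_minutes", los_minutes = "los_minutes")
}

#' Outcome summaries by ESI-N level
#'
#' For boolean outcomes (hospital admission, critical-care admission,
#' ambulance arrival, left without being seen) produces both orientations
#' of the outcome-by-level cross-tab: the within-level outcome rate
#' (`"rate"`, percent of visits at that level with the outcome) and the
#' across-level composition among outcome-positive visits (`"composition"`,
#' percent of outcome-positive visits falling at that level), plus the
#' weighted outcome-positive total per level. For duration outcomes
#' (waiting time, length of stay, minutes) produces both the weighted mean
#' with linearized CI and the weighted median with a Woodruff CI; visits
#' with missing durations are excluded with a logged count.
#'
#' @param classified Output of [classify_table()].
#' @param outcome One of `"admitted"`, `"critical_care"`, `"ambulance"`,
#'   `"lwbs"`, `"wait_minutes"`, `"los_minutes"`.
#' @param design An `esin_design`.
#' @return Tibble with `level`, `statistic`, `value`, `ci_low`, `ci_high`,
#'   `se`, `unweighted_n`, `reliable` (and `weighted_total` for booleans).
#' @export
outcome_by_level <- function(classified, outcome, design = survey_design()) {
  cols <- outcome_columns()
  if (!outcome %in% names(cols)) {
    abort(sprintf("unknown outcome '%s'; expected one of %s", outcome,
                  paste(names(cols), collapse = ", ")))
  }
  col <- cols[[outcome]]
  x <- classified[[col]]
  df <- design_frame(classified, design)
  lvl <- classified$esin_level
  rows <- list()
  if (is.logical(x)) {
    n_miss <- sum(is.na(x))
    if (n_miss > 0) {
      inform(sprintf("outcome_by_level(%s): %d visits with missing outcome excluded",
                     outcome, n_miss))
    }
    pos <- !is.na(x) & x
    for (l in 1:5) {
      dom <- lvl == l & !is.na(x)
      rate <- wrap_estimate("rate", svy_mean(as.numeric(x), df, domain = dom),
                            scale = 100)
      rate$level <- l
      comp_est <- svy_mean(as.numeric(lvl == l), df, domain = pos)
      comp_est$n <- sum(pos & lvl == l)
      comp <- wrap_estimate("composition", comp_est, scale = 100)
      comp$level <- l
      tot <- wrap_estimate("weighted_total",
                           svy_total(as.numeric(pos), df, domain = lvl == l))
      tot$level <- l
      tot$unweighted_n <- sum(pos & lvl == l)
      tot$reliable <- tot$unweighted_n >= 30L
      rows[[length(rows) + 1L]] <- dplyr::bind_rows(rate, comp, tot)
    }
  } else {
    n_miss <- sum(is.na(x))
    if (n_miss > 0) {
      inform(sprintf("outcome_by_level(%s): %d visits with missing duration excluded",
                     outcome, n_miss))
    }
    for (l in 1:5) {
      dom <- lvl == l
      m <- wrap_estimate("mean_minutes", svy_mean(x, df, domain = dom))
      m$level <- l
      med <- weighted_median_est(x, df, domain = dom)
      med$level <- l
      rows[[length(rows) + 1L]] <- dplyr::bind_rows(m, med)
    }
  }
  out <- dplyr::bind_rows(rows)
  keep <- intersect(c("level", "statistic", "value", "ci_low", "ci_high",
                      "se", "unweighted_n", "reliable"), names(out))
  out[, keep]
}

# type-1 weighted quantile: smallest x with cumulative weight >= p*W
weighted_quantile <- function(x, w, p) {
  ok <- !is.na(x) & !is.na(w)
  x <- x[ok]; w <- w[ok]
  if (!length(x)) return(NA_real_)
  o <- order(x)
  cw <- cumsum(w[o])
  x[o][which(cw >= p * sum(w))[1]]
}

# weighted median with a Woodruff interval: invert the CI of the estimated
# distribution function at the median
weighted_median_est <- function(x, df, domain = NULL) {
  d <- if (is.null(domain)) rep(TRUE, length(x)) else domain
  d <- d & !is.na(x)
  med <- weighted_quantile(x[d], df$w[d], 0.5)
  n <- sum(d)
  if (is.na(med) || n == 0) {
    return(tibble::tibble(statistic = "median_minutes", value = NA_real_,
                          ci_low = NA_real_, ci_high = NA_real_, se = NA_real_,
                          unweighted_n = 0L, reliable = FALSE))
  }
  pf <- svy_mean(as.numeric(x <= med), df, domain = d)
  z <- qnorm(0.975)
  plo <- max(0, 0.5 - z * pf$se)
  phi <- min(1, 0.5 + z * pf$se)
  tibble::tibble(
    statistic = "median_minutes", value = med,
    ci_low = weighted_quantile(x[d], df$w[d], plo),
    ci_high = weighted_quantile(x[d], df$w[d], phi),
    se = NA_real_, unweighted_n = as.integer(n), reliable = n >= 30L
  )
}

#' Compare the ESI-N distribution with recorded immediacy
#'
#' Produces the weighted ESI-N level distribution over all visits, the
#' weighted distribution of the recorded five-level immediacy item over
#' visits where it is known, and the weighted share of visits where
#' immediacy was unknown or triage was not performed (recorded `NA` or
#' `0`), reported separately.
#'
#' @param classified Output of [classify_table()].
#' @param design An `esin_design`.
#' @return List with elements `esin` (5-row share tibble), `immed` (share
#'   tibble over known immediacy levels, zero rows if none known) and
#'   `nonresponse` (1-row tibble, percent unknown/no-triage).
#' @export
immed_comparison <- function(classified, design = survey_design()) {
  df <- design_frame(classified, design)
  esin <- weighted_share_by_level(classified, design)
  unknown <- is.na(classified$immed_recorded) | classified$immed_recorded == 0L
  nr_est <- svy_mean(as.numeric(unknown), df)
  nr_est$n <- sum(unknown)
  nonresponse <- wrap_estimate("nonresponse", nr_est, scale = 100)
  known <- !unknown
  immed <- if (!any(known)) {
    tibble::tibble(level = integer(), statistic = character(), value = double(),
                   ci_low = double(), ci_high = double(), se = double(),
                   unweighted_n = integer(), reliable = logical())
  } else {
    dplyr::bind_rows(lapply(1:5, function(l) {
      dom <- known
      est <- svy_mean(as.numeric(classified$immed_recorded == l), df, domain = dom)
      est$n <- sum(known & classified$immed_recorded == l)
      row <- wrap_estimate("proportion", est, scale = 100)
      row$level <- l
      row[, c("level", "statistic", "value", "ci_low", "ci_high", "se",
              "unweighted_n", "reliable")]
    }))
  }
  list(esin = esin, immed = immed, nonresponse = nonresponse)
}

#' Emergency service areas whose recorded immediacy never reaches level 5
#'
#' Computes, per service area, the maximum recorded immediacy among visits
#' with known immediacy, and counts areas whose maximum is below five --
#' evidence of local triage schemes with fewer than five levels. Areas
#' where immediacy is always unknown are excluded from the denominator
#' (with a log message). When no service-area identifier is available the
#' result says so explicitly rather than returning a silent zero.
#'
#' @param records Canonical visit tibble (or classified table).
#' @param service_area_field Field holding the area identifier.
#' @return List: `computable`, `n_areas`, `n_below5`, `pct_below5`,
#'   `n_excluded`, and `areas`, a tibble of per-area maxima.
#' @export
max_immed_by_service_area <- function(records,
                                      service_area_field = "service_area") {
  v <- records[[service_area_field]]
  if (is.null(v) || all(is.na(v))) {
    return(list(computable = FALSE, n_areas = NA_integer_,
                n_below5 = NA_integer_, pct_below5 = NA_real_,
                n_excluded = NA_integer_,
                areas = tibble::tibble(area = character(), max_immed = integer())))
  }
  known <- !is.na(records$immed_recorded) & records$immed_recorded %in% 1:5
  keep <- !is.na(v)
  areas_all <- unique(v[keep])
  mx <- tapply(records$immed_recorded[keep & known], v[keep & known],
               max, default = NA_integer_)
  areas <- tibble::tibble(area = names(mx), max_immed = as.integer(mx))
  n_excluded <- length(setdiff(areas_all, areas$area))
  if (n_excluded > 0) {
    inform(sprintf("max_immed_by_service_area: %d area(s) with no known immediacy excluded",
                   n_excluded))
  }
  n_areas <- nrow(areas)
  n_below5 <- sum(areas$max_immed < 5L, na.rm = TRUE)
  list(computable = TRUE, n_areas = n_areas, n_below5 = n_below5,
       pct_below5 = 100 * n_below5 / n_areas, n_excluded = n_excluded,
       areas = areas)
}
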