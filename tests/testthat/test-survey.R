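cfg <- load_criteria()
srs <- survey_design(variance_method = "srs")

# five records engineered one per level, for degenerate-case checks
five_levels <- function(weights = rep(1, 5)) {
  recs <- make_records(
    cpr_flag = c(TRUE, FALSE, FALSE, FALSE, FALSE),
    rfv1 = c(NA, cfg$level2$rfv_conditions[[1]]$codes[[1]], NA, NA, NA),
    age_years = rep(40L, 5),
    services = c("", "", "CBC|XRAY", "CBC", ""),
    visit_weight = weights
  )
  quiet_classify(recs, cfg)
}

test_that("level shares handle uniform and degenerate cohorts exactly", {
  sh <- weighted_share_by_level(five_levels(), srs)
  expect_equal(sh$value, rep(20, 5))
  expect_equal(sum(sh$value), 100)
  expect_true(all(!sh$reliable))  # n = 1 per level
  one <- five_levels()[3, ]
  sh1 <- weighted_share_by_level(one, srs)
  expect_equal(sh1$value[sh1$level == 3], 100)
  expect_equal(sum(sh1$value), 100)
  expect_error(weighted_share_by_level(five_levels()[0, ], srs), "empty")
})

test_that("weighted means reproduce hand-computed values", {
  cl <- five_levels()
  m35 <- mean_level_by_group(cl[cl$esin_level %in% c(3, 5), ], NULL, srs)
  expect_equal(m35$value, 4.00)
  cl24 <- five_levels(weights = c(1, 1, 1, 3, 1))[c(2, 4), ]
  m24 <- mean_level_by_group(cl24, NULL, srs)
  expect_equal(m24$value, 3.50)  # (2*1 + 4*3) / 4
  expect_error(mean_level_by_group(cl, "no_such_field", srs), "unknown")
})

test_that("equal weights under SRS give exactly the unweighted statistics", {
  set.seed(41)
  recs <- random_records(400, cfg)
  cl <- quiet_classify(recs, cfg)
  sh <- weighted_share_by_level(cl, srs)
  expect_equal(sh$value, 100 * as.numeric(table(factor(cl$esin_level, 1:5))) / 400)
  m <- mean_level_by_group(cl, NULL, srs)
  expect_equal(m$value, mean(cl$esin_level))
  # and the SRS standard error is the classical one
  expect_equal(m$se, stats::sd(cl$esin_level) / sqrt(400), tolerance = 1e-10)
})

test_that("Taylor-linearized CI widths are invariant to weight rescaling", {
  gen <- generate_records(mixture_spec(n = 800, seed = 42), cfg)
  cl <- quiet_classify(gen$records, cfg)
  d <- survey_design()
  sh1 <- weighted_share_by_level(cl, d)
  cl2 <- cl
  cl2$visit_weight <- cl2$visit_weight * 37.5
  sh2 <- weighted_share_by_level(cl2, d)
  expect_equal(sh1$value, sh2$value, tolerance = 1e-10)
  expect_equal(sh1$ci_high - sh1$ci_low, sh2$ci_high - sh2$ci_low,
               tolerance = 1e-10)
})

test_that("single-PSU strata degrade explicitly to SRS variance", {
  cl <- five_levels()
  cl$stratum_id <- c("S1", "S1", "S2", "S2", "S3")
  cl$psu_id <- c("P1", "P1", "P2", "P3", "P4")  # S1 and S3 have one PSU
  expect_warning(weighted_share_by_level(cl, survey_design()), "single PSU")
})

test_that("boolean outcomes give both orientations plus weighted totals", {
  cl <- five_levels()
  cl$admitted_flag <- cl$esin_level == 1L
  out <- suppressMessages(outcome_by_level(cl, "admitted", srs))
  rate <- out[out$statistic == "rate", ]
  expect_equal(rate$value[rate$level == 1], 100)
  expect_equal(rate$value[rate$level != 1], rep(0, 4))
  comp <- out[out$statistic == "composition", ]
  expect_equal(comp$value[comp$level == 1], 100)
  expect_error(outcome_by_level(cl, "nonsense", srs), "unknown outcome")
})

test_that("composition shares of the positive total reproduce the level numerators", {
  gen <- generate_records(mixture_spec(n = 1500, seed = 43), cfg)
  cl <- quiet_classify(gen$records, cfg)
  out <- suppressMessages(outcome_by_level(cl, "admitted", srs))
  comp <- out[out$statistic == "composition", ]
  tot <- out[out$statistic == "weighted_total", ]
  pos_total <- sum(cl$visit_weight[cl$admitted_flag])
  expect_equal(comp$value / 100 * pos_total, tot$value, tolerance = 1e-10)
  expect_equal(sum(comp$value), 100, tolerance = 1e-8)
})

test_that("duration outcomes report weighted means and medians per level", {
  cl <- five_levels(weights = rep(1, 5))
  cl <- cl[rep(1:5, each = 10), ]
  cl$wait_minutes <- rep(c(10, 20, 30, 40, 50), each = 10)
  out <- suppressMessages(outcome_by_level(cl, "wait_minutes", srs))
  means <- out[out$statistic == "mean_minutes", ]
  meds <- out[out$statistic == "median_minutes", ]
  expect_equal(means$value, c(10, 20, 30, 40, 50))
  expect_equal(meds$value, c(10, 20, 30, 40, 50))
  # missing durations excluded with a message
  cl$wait_minutes[1] <- NA
  expect_message(outcome_by_level(cl, "wait_minutes", srs), "excluded")
})

test_that("immediacy comparison separates nonresponse and handles identity", {
  cl <- five_levels()
  cl$immed_recorded <- NA_integer_
  cmp <- immed_comparison(cl, srs)
  expect_equal(cmp$nonresponse$value, 100)
  expect_equal(nrow(cmp$immed), 0)

  cl2 <- five_levels()
  cl2$immed_recorded <- cl2$esin_level
  cmp2 <- immed_comparison(cl2, srs)
  expect_equal(cmp2$nonresponse$value, 0)
  expect_equal(cmp2$immed$value, cmp2$esin$value)
})

test_that("service areas that never use the fifth level are counted", {
  recs <- make_records(
    service_area = c("A", "A", "B", "B", "C"),
    immed_recorded = c(1L, 5L, 1L, 4L, NA)
  )
  res <- suppressMessages(max_immed_by_service_area(recs))
  expect_true(res$computable)
  expect_equal(res$n_areas, 2)       # C has no known immediacy -> excluded
  expect_equal(res$n_excluded, 1)
  expect_equal(res$n_below5, 1)      # only B tops out below 5
  expect_equal(res$pct_below5, 50)
  all5 <- make_records(service_area = c("A", "B"), immed_recorded = c(5L, 5L))
  expect_equal(max_immed_by_service_area(all5)$n_below5, 0)
  none <- make_records(immed_recorded = 3L)
  expect_false(max_immed_by_service_area(none)$computable)
})

test_that("the unweighted-n reliability rule flags small cells", {
  set.seed(44)
  recs <- random_records(200, cfg)
  cl <- quiet_classify(recs, cfg)
  sh <- weighted_share_by_level(cl, srs)
  expect_equal(sh$reliable, sh$unweighted_n >= 30)
})
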