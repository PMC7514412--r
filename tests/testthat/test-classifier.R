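cfg <- load_criteria()

lvl <- function(...) quiet_classify(make_records(...), cfg)$esin_level

test_that("stepwise assignment reproduces the canonical examples", {
  # CPR with plenty of resources is still level 1
  expect_equal(lvl(cpr_flag = TRUE, services = "CBC|XRAY|IVFLUIDS"), 1L)
  # adult bradycardia
  expect_equal(lvl(age_years = 30L, pulse_bpm = 45L), 1L)
  # the same pulse under the age gate is not level 1; no resources -> 5
  expect_equal(lvl(age_years = 20L, pulse_bpm = 45L), 5L)
  # adult hypotension
  expect_equal(lvl(age_years = 30L, bp_systolic_mmhg = 78L), 1L)
  # level-2 complaint dominates resource-based level 3
  sob <- Filter(function(x) x$name == "Shortness of breath/breathing problem",
                cfg$level2$rfv_conditions)[[1]]
  expect_equal(lvl(rfv1 = sob$codes[[1]], age_years = 40L,
                   services = "CBC|XRAY"), 2L)
  # no criteria: resources partition 3/4/5
  expect_equal(lvl(age_years = 40L, services = "CBC|XRAY"), 3L)
  expect_equal(lvl(age_years = 40L, services = "CBC"), 4L)
  expect_equal(lvl(age_years = 40L), 5L)
  # severe pain and pediatric fever are level 3 floors
  expect_equal(lvl(age_years = 40L, pain_level = 4L), 3L)
  expect_equal(lvl(age_years = 1L, temp_f = 101.5), 3L)
  # motor vehicle accident
  mva <- cfg$level3$motor_vehicle_accident
  expect_equal(lvl(age_years = 40L, rfv3 = mva$codes[[1]]), 3L)
  # a record with nothing but a weight still classifies (to level 5)
  expect_equal(lvl(), 5L)
})

test_that("the audit trail records every fired criterion with its level", {
  rec <- make_records(cpr_flag = TRUE, age_years = 30L, pulse_bpm = 45L,
                      pain_level = 4L, services = "CBC|XRAY")
  out <- quiet_classify(rec, cfg)
  expect_equal(out$esin_level, 1L)
  trail <- strsplit(out$matched_criteria, "|", fixed = TRUE)[[1]]
  expect_true("1:Cardiopulmonary resuscitation" %in% trail)
  expect_true("1:Pulse \u226450 and age >25" %in% trail)
  expect_true("3:Severe pain" %in% trail)
  expect_true("3:More than 1 resource used" %in% trail)
  # trail levels are ordered and their minimum is the assigned level
  lv <- as.integer(sub(":.*", "", trail))
  expect_equal(min(lv), out$esin_level)
  expect_false(is.unsorted(lv))
})

test_that("classify_table preserves order, count and row independence", {
  set.seed(31)
  recs <- random_records(200, cfg)
  out <- quiet_classify(recs, cfg)
  expect_equal(nrow(out), 200)
  expect_equal(out$visit_id, recs$visit_id)
  # shuffling rows permutes but never changes the per-visit level
  perm <- sample(200)
  out2 <- quiet_classify(recs[perm, ], cfg)
  expect_equal(out2$esin_level, out$esin_level[perm])
  # empty in, empty out
  e <- quiet_classify(empty_records(), cfg)
  expect_equal(nrow(e), 0)
  expect_true(all(c("esin_level", "matched_criteria") %in% names(e)))
  # one engineered record per level
  five <- make_records(
    cpr_flag = c(TRUE, FALSE, FALSE, FALSE, FALSE),
    rfv1 = c(NA, cfg$level2$rfv_conditions[[1]]$codes[[1]], NA, NA, NA),
    age_years = rep(40L, 5),
    services = c("", "", "CBC|XRAY", "CBC", "")
  )
  expect_equal(quiet_classify(five, cfg)$esin_level, 1:5)
})

test_that("assign_level matches classify_table on single records", {
  set.seed(32)
  recs <- random_records(50, cfg)
  whole <- quiet_classify(recs, cfg)
  each <- vapply(seq_len(50), function(i) {
    suppressWarnings(assign_level(recs[i, ], cfg))$esin_level
  }, integer(1))
  expect_equal(each, whole$esin_level)
})

test_that("missing fields never fire criteria and never block classification", {
  # all-missing record classifies; vital-dependent criteria need the vital
  rec <- make_records(age_years = NA_integer_)
  expect_equal(quiet_classify(rec, cfg)$esin_level, 5L)
  # age-gated level-1 vitals require a known age
  expect_equal(lvl(pulse_bpm = 40L), 5L)
})
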