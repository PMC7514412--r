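cfg <- load_criteria()

test_that("shipped configuration carries the full condition inventory", {
  expect_s3_class(cfg, "esin_criteria")
  expect_length(cfg$level1$rfv_conditions, 5)
  expect_length(cfg$level2$rfv_conditions, 15)
  expect_gte(length(cfg$level2$vital_bands), 3)
  expect_length(cfg$level1$flags, 3)
  expect_length(cfg$level1$vitals, 2)
  # adult level-1 vital thresholds as published
  vit <- cfg$level1$vitals
  pulse <- vit[[which(vapply(vit, `[[`, character(1), "vital") == "pulse_bpm")]]
  bp <- vit[[which(vapply(vit, `[[`, character(1), "vital") == "bp_systolic_mmhg")]]
  expect_equal(pulse$le, 50)
  expect_equal(pulse$age_gt_years, 25)
  expect_equal(bp$le, 80)
  expect_equal(bp$age_gt_years, 25)
})

test_that("incomplete or inconsistent configurations fail loudly", {
  broken <- unclass(cfg)
  broken$level2$rfv_conditions <- Filter(
    function(x) x$name != "Sepsis, septicemia", broken$level2$rfv_conditions)
  p1 <- tempfile(fileext = ".yaml")
  yaml::write_yaml(broken, p1)
  expect_error(load_criteria(p1), "Sepsis, septicemia")

  overlapping <- unclass(cfg)
  overlapping$level2$vital_bands <- list(
    list(age_min_days = 0, age_max_days = 90, pulse_gt = 180),
    list(age_min_days = 60, age_max_days = 365, pulse_gt = 160)
  )
  p2 <- tempfile(fileext = ".yaml")
  yaml::write_yaml(overlapping, p2)
  expect_error(load_criteria(p2), "overlap")

  empty_codes <- unclass(cfg)
  empty_codes$level1$rfv_conditions[[1]]$codes <- list()
  p3 <- tempfile(fileext = ".yaml")
  yaml::write_yaml(empty_codes, p3)
  expect_error(load_criteria(p3), "empty RFV code set")
})

test_that("configuration round-trips through YAML and JSON", {
  for (ext in c(".yaml", ".json")) {
    p <- tempfile(fileext = ext)
    write_criteria(cfg, p)
    back <- load_criteria(p)
    expect_equal(unclass(back), unclass(cfg), tolerance = 1e-12)
  }
})

test_that("RFV matching honors code sets, empty records and age gates", {
  syncope <- Filter(function(x) x$name == "Fainting (Syncope)",
                    cfg$level2$rfv_conditions)[[1]]
  hit <- make_records(rfv2 = syncope$codes[[1]], age_years = 40L)
  expect_true(match_rfv(hit, syncope))
  none <- make_records(age_years = 40L)
  expect_false(match_rfv(none, syncope))

  elderly <- Filter(function(x) x$name == "Abdominal pain (elderly)",
                    cfg$level2$rfv_conditions)[[1]]
  young <- make_records(rfv1 = elderly$codes[[1]], age_years = 30L)
  expect_false(match_rfv(young, elderly))
  old <- make_records(rfv1 = elderly$codes[[1]], age_years = 70L)
  expect_true(match_rfv(old, elderly))
  ageless <- make_records(rfv1 = elderly$codes[[1]])
  expect_false(match_rfv(ageless, elderly))  # missing age fails a gated set

  # all-of condition needs every family among the three codes
  trio <- Filter(function(x) !is.null(x$all_of), cfg$level2$rfv_conditions)[[1]]
  fams <- vapply(trio$all_of, function(g) unlist(g)[1], numeric(1))
  expect_true(match_rfv(make_records(rfv1 = fams[1], rfv2 = fams[2], rfv3 = fams[3],
                                     age_years = 30L), trio))
  expect_false(match_rfv(make_records(rfv1 = fams[1], rfv2 = fams[2],
                                      age_years = 30L), trio))
})

test_that("match_rfv is monotone in the code set", {
  set.seed(11)
  recs <- random_records(300, cfg)
  base <- Filter(function(x) x$name == "Fainting (Syncope)",
                 cfg$level2$rfv_conditions)[[1]]
  wider <- base
  wider$codes <- c(base$codes, list(20050L))
  expect_true(all(match_rfv(recs, base) <= match_rfv(recs, wider)))
})

test_that("danger-zone vitals fire on present exceedance only", {
  bands <- cfg$level2$vital_bands
  expect_true(danger_zone_vitals(
    make_records(age_years = 30L, pulse_bpm = 101L), bands))
  expect_false(danger_zone_vitals(
    make_records(age_years = 30L, pulse_bpm = 100L), bands))  # strict exceed
  expect_false(danger_zone_vitals(
    make_records(age_years = 30L), bands))                    # missing vital
  expect_false(danger_zone_vitals(
    make_records(pulse_bpm = 190L), bands))                   # missing age
  # age outside every band of a truncated table
  infant_only <- bands[1]
  expect_false(danger_zone_vitals(
    make_records(age_years = 30L, pulse_bpm = 190L), infant_only))
  # young-infant fever fires on temperature
  expect_true(danger_zone_vitals(
    make_records(age_years = 0L, age_days = 10L, temp_f = 100.4), bands))
})

test_that("removing a vital sign can never flip danger-zone to true", {
  set.seed(12)
  recs <- random_records(500, cfg)
  before <- danger_zone_vitals(recs, cfg$level2$vital_bands)
  for (f in c("pulse_bpm", "temp_f", "bp_systolic_mmhg")) {
    blanked <- recs
    blanked[[f]] <- NA
    after <- danger_zone_vitals(blanked, cfg$level2$vital_bands)
    expect_true(all(after <= before))
  }
})
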