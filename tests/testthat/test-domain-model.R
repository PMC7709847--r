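test_that("activity-year invariants are enforced with path-anchored messages", {
  ok <- activity_year("2016-2017", 1136, 82, 612, 524, 915, 221, 318)
  expect_s3_class(ok, "teleroi_activity")
  expect_identical(ok$total_bookings, 1136L)

  bad <- list(
    list(args = list("y", 100, 10, 60, 30, 80, 20, 10),
         why = "new \\+ review split must sum"),
    list(args = list("y", 100, 10, 60, 40, 70, 20, 10),
         why = "adult \\+ pediatric split must sum"),
    list(args = list("y", 100, 10, 60, 40, 80, 20, 101),
         why = "fta_count cannot exceed"),
    list(args = list("y", -5, 10, -5, 0, -5, 0, 0),
         why = "non-negative")
  )
  for (case in bad) {
    expect_validation_error(do.call(activity_year, case$args))
  }
  # errors carry a path into the document
  err <- tryCatch(activity_year("2099-2100", 10, 1, 5, 5, 8, 2, 11),
                  error = function(e) conditionMessage(e))
  expect_match(err, "activity\\[2099-2100\\]")
})

test_that("staff lines validate rates and reject implausible reported costs", {
  expect_validation_error(staff_line("x", -1, 0.29, 4, "s"))
  expect_validation_error(staff_line("x", 10, -0.1, 4, "s"))
  # reported cost within 5 cents of the formula is accepted, beyond rejected
  expect_silent(staff_line("radiographer", 50.61, 0.29, 4, "s",
                           reported_line_cost = 261.13))
  expect_validation_error(staff_line("radiographer", 50.61, 0.29, 4, "s",
                                     reported_line_cost = 262.00),
                          "diverges")
})

test_that("care models reject dangling site references", {
  sites <- data.frame(site_id = "a", role = "provider")
  line_elsewhere <- staff_line("r", 10, 0.29, 1, "zz")
  expect_validation_error(
    care_model("m", sites, line_elsewhere), "unknown site 'zz'")
  expect_validation_error(
    care_model("m", sites, staff_line("r", 10, 0.29, 1, "a"),
               income_claims = list(zz = "prov")), "unknown site 'zz'")
  expect_validation_error(
    care_model("m", data.frame(site_id = "a", role = "boss"),
               staff_line("r", 10, 0.29, 1, "a")), "unknown site role")
})

test_that("scenario assembly validates cross-references", {
  scen <- tiny_scenario()
  expect_s3_class(scen, "teleroi_scenario")
  # stream must carry a rate for every activity year
  bad_stream <- funding_stream("prov", c("2016-2017" = 60))
  expect_validation_error(
    scenario(scen$models, scen$activity, list(bad_stream, scen$streams$rec),
             scen$schedules),
    "no rate for year '2015-2016'")
  # discount schedule must exist
  m <- scen$models$duo
  m$discount_schedule_id <- "nope"
  expect_validation_error(
    scenario(list(m), scen$activity, scen$streams, scen$schedules),
    "unknown discount schedule")
})

test_that("bundled case-study document loads with all cross-references resolved", {
  scen <- fracture_clinic_scenario()
  expect_length(scen$models, 3)
  expect_identical(nrow(scen$activity), 3L)
  expect_length(scen$streams, 3)
  expect_identical(scen$base_year, "2016-2017")
  # the travel-model referral site claims no income stream and earns zero
  travel <- scen$models$travel
  expect_null(travel$income_claims[["rural"]])
  act <- scen$activity[3, ]
  expect_identical(annual_income(travel, "rural", act, scen$streams), 0)
})

test_that("broken documents are rejected with a path into the document", {
  scen_path <- system.file("extdata", "fracture_clinic.yaml", package = "teleroi")
  doc <- yaml::read_yaml(scen_path)
  doc$activity[[1]]$fta_count <- 400  # exceeds 321 bookings
  tmp <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(doc, tmp)
  err <- tryCatch(load_scenario(tmp), error = function(e) conditionMessage(e))
  expect_match(err, "activity\\[2014-2015\\]")
  expect_match(err, "fta_count")

  doc <- yaml::read_yaml(scen_path)
  doc$schema_version <- 99
  yaml::write_yaml(doc, tmp)
  expect_validation_error(load_scenario(tmp), "schema_version")
})

test_that("FTA given as a rate converts by half-up rounding; a count wins over a rate", {
  doc <- list(
    schema_version = 1,
    activity = list(list(financial_year = "y1", total_bookings = 321,
                         clinics_held = 31, new_bookings = 175,
                         review_bookings = 146, adult_bookings = 279,
                         pediatric_bookings = 42, fta_rate = 0.165)),
    funding_streams = list(list(stream_id = "s", rates = list(y1 = 10))),
    discount_schedules = list(base = list(base_year = "y1")),
    care_models = list(list(
      model_id = "m", discount_schedule = "base",
      sites = list(list(site_id = "a", role = "provider")),
      staff_lines = list(list(site_id = "a", role_name = "r", hourly_rate = 10,
                              on_cost_fraction = 0.29, hours_per_clinic = 1)),
      income_claims = list(a = list("s"))))
  )
  tmp <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(doc, tmp)
  scen <- load_scenario(tmp)
  expect_identical(scen$activity$fta_count, as.integer(round_half_up(0.165 * 321)))

  doc$activity[[1]]$fta_count <- 53  # count takes precedence over the rate
  yaml::write_yaml(doc, tmp)
  expect_identical(load_scenario(tmp)$activity$fta_count, 53L)
})

test_that("on-cost fractions outside the configured set are rejected on load", {
  scen_path <- system.file("extdata", "fracture_clinic.yaml", package = "teleroi")
  doc <- yaml::read_yaml(scen_path)
  doc$care_models[[1]]$staff_lines[[1]]$on_cost_fraction <- 0.31
  doc$care_models[[1]]$staff_lines[[1]]$line_cost <- NULL
  tmp <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(doc, tmp)
  expect_validation_error(load_scenario(tmp), "on_cost_fraction 0.31")
})

test_that("activity tables round-trip losslessly through CSV", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  fixture_act <- fracture_clinic_scenario()$activity
  write_activity_table(fixture_act, tmp)
  again <- read_activity_table(tmp)
  expect_equal(as.data.frame(again), as.data.frame(fixture_act))

  gen <- generate_activity(activity_generator_config(seed = 1))
  write_activity_table(gen, tmp)
  expect_equal(as.data.frame(read_activity_table(tmp)), as.data.frame(gen))

  expect_validation_error(write_activity_table(fixture_act[0, ], tmp))
})

test_that("load -> write -> load is the identity on scenarios", {
  tmp <- withr::local_tempfile(fileext = ".yaml")
  for (scen in list(fracture_clinic_scenario(), tiny_scenario())) {
    write_scenario(scen, tmp)
    again <- load_scenario(tmp)
    expect_equal(again$activity, scen$activity)
    expect_equal(again$streams, scen$streams, tolerance = 1e-12)
    expect_equal(lapply(again$schedules, `[[`, "factor_by_year"),
                 lapply(scen$schedules, `[[`, "factor_by_year"),
                 tolerance = 1e-12)
    # the evaluated results must be identical, not just the raw config
    expect_equal(run_scenario(again), run_scenario(scen))
  }
})
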