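# Builders for small in-code scenarios used across tests.

tiny_activity <- function() {
  activity_table(
    activity_year("2015-2016", 100, 10, 60, 40, 80, 20, 20),
    activity_year("2016-2017", 200, 20, 110, 90, 150, 50, 50)
  )
}

tiny_scenario <- function(uptake = 0.2, claimant_cost = 100) {
  act <- tiny_activity()
  streams <- list(
    funding_stream("prov", c("2015-2016" = 50, "2016-2017" = 60)),
    funding_stream("rec", c("2015-2016" = 20, "2016-2017" = 25))
  )
  sched <- discount_schedule("2016-2017",
                             periods_back = c("2015-2016" = 1, "2016-2017" = 0),
                             annual_rate = 0.025, id = "staffing")
  lines <- dplyr::bind_rows(
    staff_line("doctor", 100, 0.23, 4, "a"),
    staff_line("nurse", 40, 0.29, 4, "b")
  )
  m1 <- care_model("duo",
                   sites = data.frame(site_id = c("a", "b"),
                                      role = c("provider", "referral")),
                   staff_lines = lines,
                   income_claims = list(a = "prov", b = "rec"),
                   discount_schedule_id = "staffing")
  m2 <- care_model("subsidised",
                   sites = data.frame(site_id = c("a", "b"),
                                      role = c("provider", "referral")),
                   staff_lines = lines[1, ],
                   income_claims = list(a = "prov"),
                   travel_policy = list(
                     site_id = "b",
                     policy = travel_subsidy_policy(uptake, claimant_cost)),
                   discount_schedule_id = "staffing")
  scenario(list(m1, m2), act, streams, list(sched))
}

# a random small scenario for property tests (single model/site)
random_staff_model <- function(n_lines, site = "s") {
  lines <- dplyr::bind_rows(lapply(seq_len(n_lines), function(i) {
    staff_line(paste0("role", i),
               hourly_rate = round(stats::runif(1, 10, 200), 2),
               on_cost_fraction = sample(c(0.23, 0.29), 1),
               hours_per_clinic = sample(1:10, 1),
               site_id = site)
  }))
  care_model("rand", sites = data.frame(site_id = site, role = "provider"),
             staff_lines = lines, discount_schedule_id = "staffing")
}

expect_validation_error <- function(expr, pattern = NULL) {
  expect_error(expr, regexp = pattern, class = "teleroi_validation_error")
}
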