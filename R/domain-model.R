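#' Staffing resource on one site
#'
#' One line of the per-clinic human-resource cost model: a role paid an
#' hourly rate, loaded with an employer on-cost fraction, for a fixed number
#' of hours per clinic session. Wage agreements in the modelled setting add
#' 23% on-costs for medical officers and 29% for all other staff, so those
#' are the values scenario documents normally restrict themselves to.
#'
#' `reported_line_cost` optionally carries an externally published per-clinic
#' cost for the line (in A$). When present it is preferred over the
#' `hourly_rate * (1 + on_cost_fraction) * hours_per_clinic` formula by
#' [site_clinic_cost()]; published cost tables are sometimes rounded with
#' a few cents of arithmetic noise, and treating them as authoritative lets
#' totals reproduce the source exactly. A divergence above A$0.05 from the
#' formula is rejected as a likely transcription error.
#'
#' @param role_name text label for the role.
#' @param hourly_rate base wage, A$/hour, base-year prices.
#' @param on_cost_fraction employer on-cost loading as a proportion (0.23, 0.29).
#' @param hours_per_clinic hours the role is engaged per clinic session.
#' @param site_id site bearing the cost.
#' @param reported_line_cost optional published per-clinic cost, A$.
#' @return one-row tibble of class `teleroi_staff_line`.
#' @examples
#' staff_line("Orthopedic specialist", 134.57, 0.23, 4, "rural")
#' @export
staff_line <- function(role_name, hourly_rate, on_cost_fraction,
                       hours_per_clinic, site_id, reported_line_cost = NULL) {
  check_nonneg(hourly_rate, "hourly_rate")
  check_nonneg(on_cost_fraction, "on_cost_fraction")
  check_nonneg(hours_per_clinic, "hours_per_clinic")
  if (is.null(reported_line_cost)) reported_line_cost <- NA_real_
  if (!is.na(reported_line_cost)) {
    check_nonneg(reported_line_cost, "reported_line_cost")
    formula_cost <- round_money(hourly_rate * (1 + on_cost_fraction) * hours_per_clinic)
    if (abs(reported_line_cost - formula_cost) > 0.05) {
      abort_validation(sprintf(
        "reported_line_cost %.2f diverges from computed %.2f by more than A$0.05 for role '%s'",
        reported_line_cost, formula_cost, role_name))
    }
  }
  out <- tibble(
    site_id = as.character(site_id),
    role_name = as.character(role_name),
    hourly_rate = as.numeric(hourly_rate),
    on_cost_fraction = as.numeric(on_cost_fraction),
    hours_per_clinic = as.numeric(hours_per_clinic),
    reported_line_cost = as.numeric(reported_line_cost)
  )
  class(out) <- c("teleroi_staff_line", class(out))
  out
}

#' Travel-subsidy policy
#'
#' Models a patient travel subsidy scheme as an uptake fraction of a base
#' population, each claimant costing a fixed average amount. The base
#' population is either all bookings for the year or only attended bookings.
#'
#' @param uptake_fraction proportion of the base population claiming.
#' @param average_cost_per_claimant A$ per claimant.
#' @param base_population `"all_bookings"` or `"attended_only"`.
#' @return list of class `teleroi_travel_policy`.
#' @export
travel_subsidy_policy <- function(uptake_fraction, average_cost_per_claimant,
                                  base_population = c("all_bookings", "attended_only")) {
  check_proportion(uptake_fraction, "uptake_fraction")
  check_nonneg(average_cost_per_claimant, "average_cost_per_claimant")
  base_population <- match.arg(base_population)
  structure(
    list(uptake_fraction = uptake_fraction,
         average_cost_per_claimant = average_cost_per_claimant,
         base_population = base_population),
    class = "teleroi_travel_policy"
  )
}

#' Activity-based funding stream
#'
#' A funding stream reimburses a fixed amount per attended appointment; the
#' amount varies by financial year. In the modelled Australian setting the
#' streams correspond to National Weighted Activity Unit (NWAU) clinic
#' classes claimed by the consultant-provider and patient-recipient sides
#' of a consultation; the per-appointment dollar rates are exogenous inputs
#' (they can be calibrated from published income with
#' [calibrate_funding_rates()]).
#'
#' @param stream_id identifier used by care-model income claims.
#' @param rate_by_year named numeric vector, A$ per attended appointment,
#'   names are financial-year labels.
#' @param label human-readable description.
#' @return list of class `teleroi_funding_stream`.
#' @export
funding_stream <- function(stream_id, rate_by_year, label = stream_id) {
  if (is.null(names(rate_by_year)) || any(!nzchar(names(rate_by_year)))) {
    abort_validation("rate_by_year must be named by financial-year label",
                     sprintf("funding_streams[%s]", stream_id))
  }
  for (yr in names(rate_by_year)) {
    check_nonneg(rate_by_year[[yr]], sprintf("rate for %s", yr),
                 sprintf("funding_streams[%s].rates", stream_id))
  }
  structure(
    list(stream_id = as.character(stream_id), label = as.character(label),
         rate_by_year = unlist(rate_by_year)),
    class = "teleroi_funding_stream"
  )
}

#' Multi-year price discount schedule
#'
#' Holds a multiplicative factor per financial year, relative to a base year
#' whose factor is exactly 1. Factors may be given directly, or derived from
#' an annual discount rate and a number of periods back from base
#' (`factor = 1 / (1 + annual_rate)^periods`), the divisive convention used
#' for back-casting base-year wages to earlier years.
#'
#' @param base_year financial-year label with factor 1.
#' @param factor_by_year named numeric vector of factors; or `NULL` if
#'   `periods_back` is given.
#' @param periods_back named integer vector of discounting periods per year.
#' @param annual_rate annual discount rate (e.g. 0.025) used with
#'   `periods_back`.
#' @param id optional schedule identifier.
#' @return list of class `teleroi_discount_schedule`.
#' @examples
#' discount_schedule("2016-2017",
#'   periods_back = c("2014-2015" = 3, "2015-2016" = 1, "2016-2017" = 0),
#'   annual_rate = 0.025)
#' @export
discount_schedule <- function(base_year, factor_by_year = NULL,
                              periods_back = NULL, annual_rate = 0.025,
                              id = NULL) {
  path <- if (is.null(id)) "discount_schedule" else sprintf("discount_schedules[%s]", id)
  if (is.null(factor_by_year) && is.null(periods_back)) {
    # degenerate but legal: only the base year, factor 1
    factor_by_year <- stats::setNames(1, base_year)
  } else if (is.null(factor_by_year)) {
    check_nonneg(annual_rate, "annual_rate", path)
    factor_by_year <- 1 / (1 + annual_rate)^unlist(periods_back)
  } else {
    factor_by_year <- unlist(factor_by_year)
  }
  if (is.null(names(factor_by_year)) || any(!nzchar(names(factor_by_year)))) {
    abort_validation("factors must be named by financial-year label", path)
  }
  if (any(factor_by_year <= 0)) abort_validation("all factors must be > 0", path)
  if (!base_year %in% names(factor_by_year)) {
    factor_by_year[[base_year]] <- 1
  } else if (abs(factor_by_year[[base_year]] - 1) > 1e-12) {
    abort_validation(sprintf("factor for base year %s must be exactly 1", base_year), path)
  }
  structure(
    list(id = id, base_year = as.character(base_year), factor_by_year = factor_by_year),
    class = "teleroi_discount_schedule"
  )
}

#' One financial year of aggregate clinic activity
#'
#' Aggregate bookings for a clinic over one financial year, with the
#' new/review and adult/pediatric splits and the failed-to-attend (FTA)
#' count. Splits must each sum to the booking total; FTA cannot exceed it.
#'
#' @param year_label financial-year text, e.g. `"2016-2017"`. Labels are
#'   opaque ordered strings: chronological order is the order rows appear in
#'   an activity table, never parsed from the label.
#' @param total_bookings,clinics_held,new_bookings,review_bookings
#'   non-negative integers.
#' @param adult_bookings,pediatric_bookings,fta_count non-negative integers.
#' @return one-row tibble of class `teleroi_activity`.
#' @examples
#' activity_year("2016-2017", 1136, 82, 612, 524, 915, 221, 318)
#' @export
activity_year <- function(year_label, total_bookings, clinics_held,
                          new_bookings, review_bookings,
                          adult_bookings, pediatric_bookings, fta_count) {
  path <- sprintf("activity[%s]", year_label)
  for (f in c("total_bookings", "clinics_held", "new_bookings", "review_bookings",
              "adult_bookings", "pediatric_bookings", "fta_count")) {
    v <- get(f)
    check_nonneg(v, f, path)
    if (abs(v - round(v)) > 1e-9) abort_validation(sprintf("%s must be a whole number", f), path)
  }
  if (new_bookings + review_bookings != total_bookings) {
    abort_validation("new_bookings + review_bookings must equal total_bookings", path)
  }
  if (adult_bookings + pediatric_bookings != total_bookings) {
    abort_validation("adult_bookings + pediatric_bookings must equal total_bookings", path)
  }
  if (fta_count > total_bookings) {
    abort_validation("fta_count cannot exceed total_bookings", path)
  }
  out <- tibble(
    year_label = as.character(year_label),
    total_bookings = as.integer(total_bookings),
    clinics_held = as.integer(clinics_held),
    new_bookings = as.integer(new_bookings),
    review_bookings = as.integer(review_bookings),
    adult_bookings = as.integer(adult_bookings),
    pediatric_bookings = as.integer(pediatric_bookings),
    fta_count = as.integer(fta_count)
  )
  class(out) <- c("teleroi_activity", class(out))
  out
}

#' Bind and validate activity-year rows
#'
#' @param ... one-row activity tibbles from [activity_year()], or data frames
#'   with the same columns.
#' @return tibble of class `teleroi_activity`, one row per year, in the order
#'   given (which defines chronological order).
#' @export
activity_table <- function(...) {
  rows <- list(...)
  if (length(rows) == 1 && is.data.frame(rows[[1]])) rows <- list(rows[[1]])
  df <- bind_rows(lapply(rows, as.data.frame))
  if (nrow(df) == 0) abort_validation("activity table must have at least one year", "activity")
  out <- bind_rows(lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    activity_year(r$year_label, r$total_bookings, r$clinics_held,
                  r$new_bookings, r$review_bookings,
                  r$adult_bookings, r$pediatric_bookings, r$fta_count)
  }))
  if (anyDuplicated(out$year_label)) {
    abort_validation("duplicate year_label in activity table", "activity")
  }
  class(out) <- c("teleroi_activity", class(out))
  out
}

# select one year's row, with a path-anchored error
activity_row <- function(activity, year_label) {
  i <- match(year_label, activity$year_label)
  if (is.na(i)) {
    abort_validation(sprintf("year '%s' not present in activity table", year_label), "activity")
  }
  activity[i, ]
}

#' Care-delivery model configuration
#'
#' A named service-delivery configuration: which sites participate (with
#' referral/provider roles), which staff lines each site pays for, which
#' funding streams each site claims income from, and an optional travel
#' subsidy borne by one site. A site absent from `income_claims` earns zero
#' income (e.g. the referral site under a patient-travel model).
#'
#' @param model_id identifier, conventionally one of `"telehealth"`,
#'   `"travel"`, `"virtual_practitioner"`, but free text is accepted.
#' @param sites data frame with columns `site_id`, `role`
#'   (`"referral"`/`"provider"`) and optional `label`.
#' @param staff_lines tibble of [staff_line()] rows (may be empty).
#' @param income_claims named list: site_id -> character vector of stream ids.
#' @param travel_policy optional list `list(site_id =, policy =)` where
#'   `policy` is a [travel_subsidy_policy()].
#' @param discount_schedule_id id of the discount schedule this model's
#'   costs use (resolved against the scenario's schedules).
#' @param label human-readable description.
#' @return list of class `teleroi_care_model`.
#' @export
care_model <- function(model_id, sites, staff_lines, income_claims = list(),
                       travel_policy = NULL, discount_schedule_id = "staffing",
                       label = model_id) {
  path <- sprintf("care_models[%s]", model_id)
  sites <- as_tibble(as.data.frame(sites))
  if (!all(c("site_id", "role") %in% names(sites)) || nrow(sites) == 0) {
    abort_validation("sites must be a non-empty data frame with site_id and role", path)
  }
  if (!"label" %in% names(sites)) sites$label <- sites$site_id
  if (anyDuplicated(sites$site_id)) abort_validation("duplicate site_id", paste0(path, ".sites"))
  bad_role <- setdiff(unique(sites$role), c("referral", "provider"))
  if (length(bad_role)) {
    abort_validation(sprintf("unknown site role '%s'", bad_role[1]), paste0(path, ".sites"))
  }
  if (is.null(staff_lines) || nrow(as.data.frame(staff_lines)) == 0) {
    staff_lines <- staff_line("placeholder", 0, 0, 0, sites$site_id[1])[0, ]
  } else {
    staff_lines <- as_tibble(as.data.frame(staff_lines))
  }
  unknown <- setdiff(unique(staff_lines$site_id), sites$site_id)
  if (length(unknown)) {
    abort_validation(sprintf("staff line references unknown site '%s'", unknown[1]),
                     paste0(path, ".staff_lines"))
  }
  unknown <- setdiff(names(income_claims), sites$site_id)
  if (length(unknown)) {
    abort_validation(sprintf("income claim references unknown site '%s'", unknown[1]),
                     paste0(path, ".income_claims"))
  }
  if (!is.null(travel_policy)) {
    if (!travel_policy$site_id %in% sites$site_id) {
      abort_validation(sprintf("travel policy references unknown site '%s'",
                               travel_policy$site_id), paste0(path, ".travel_policy"))
    }
    if (!inherits(travel_policy$policy, "teleroi_travel_policy")) {
      abort_validation("travel_policy$policy must be a travel_subsidy_policy()",
                       paste0(path, ".travel_policy"))
    }
  }
  structure(
    list(model_id = as.character(model_id), label = as.character(label),
         sites = sites, staff_lines = staff_lines,
         income_claims = lapply(income_claims, as.character),
         travel_policy = travel_policy,
         discount_schedule_id = as.character(discount_schedule_id)),
    class = "teleroi_care_model"
  )
}

#' Assemble and cross-validate a scenario
#'
#' Binds care models, activity, funding streams and discount schedules into
#' one validated scenario object. Cross-references are checked: every model's
#' discount schedule must exist, every claimed funding stream must exist and
#' must carry a rate for every activity year, and every discount schedule
#' must cover every activity year.
#'
#' @param models list of [care_model()] objects.
#' @param activity a [activity_table()].
#' @param streams list of [funding_stream()] objects.
#' @param schedules named list of [discount_schedule()] objects.
#' @param base_year reference financial year (defaults to the last activity
#'   year); used as the default breakeven reference year.
#' @param schema_version integer document schema version.
#' @return list of class `teleroi_scenario`.
#' @export
scenario <- function(models, activity, streams, schedules,
                     base_year = NULL, schema_version = 1L) {
  if (!inherits(activity, "teleroi_activity")) activity <- activity_table(activity)
  if (inherits(models, "teleroi_care_model")) models <- list(models)
  names(models) <- vapply(models, `[[`, "", "model_id")
  if (inherits(streams, "teleroi_funding_stream")) streams <- list(streams)
  names(streams) <- vapply(streams, `[[`, "", "stream_id")
  names(schedules) <- vapply(schedules, function(s) {
    if (is.null(s$id)) "" else s$id
  }, "")
  if (any(!nzchar(names(schedules)))) {
    abort_validation("every discount schedule needs an id", "discount_schedules")
  }
  if (is.null(base_year)) base_year <- activity$year_label[nrow(activity)]
  years <- activity$year_label
  for (m in models) {
    path <- sprintf("care_models[%s]", m$model_id)
    if (!m$discount_schedule_id %in% names(schedules)) {
      abort_validation(sprintf("unknown discount schedule '%s'", m$discount_schedule_id), path)
    }
    for (sid in names(m$income_claims)) {
      for (st in m$income_claims[[sid]]) {
        if (!st %in% names(streams)) {
          abort_validation(sprintf("unknown funding stream '%s'", st),
                           sprintf("%s.income_claims[%s]", path, sid))
        }
        missing_years <- setdiff(years, names(streams[[st]]$rate_by_year))
        if (length(missing_years)) {
          abort_validation(
            sprintf("funding stream '%s' has no rate for year '%s'", st, missing_years[1]),
            sprintf("funding_streams[%s].rates", st))
        }
      }
    }
  }
  for (sch in schedules) {
    missing_years <- setdiff(years, names(sch$factor_by_year))
    if (length(missing_years)) {
      abort_validation(sprintf("no factor for year '%s'", missing_years[1]),
                       sprintf("discount_schedules[%s]", sch$id))
    }
  }
  structure(
    list(schema_version = as.integer(schema_version), base_year = base_year,
         models = models, activity = activity, streams = streams,
         schedules = schedules),
    class = "teleroi_scenario"
  )
}

#' @export
print.teleroi_scenario <- function(x, ...) {
  cat(sprintf("<teleroi scenario> schema v%d, base year %s\n",
              x$schema_version, x$base_year))
  cat(sprintf("  %d care model(s): %s\n", length(x$models),
              paste(names(x$models), collapse = ", ")))
  cat(sprintf("  %d activity year(s): %s\n", nrow(x$activity),
              paste(x$activity$year_label, collapse = ", ")))
  cat(sprintf("  %d funding stream(s): %s\n", length(x$streams),
              paste(names(x$streams), collapse = ", ")))
  invisible(x)
}
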