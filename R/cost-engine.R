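#' Per-clinic cost of one staff line
#'
#' `hourly_rate * (1 + on_cost_fraction) * hours_per_clinic`, rounded half-up
#' to cents. With `prefer_reported = TRUE`, a published `reported_line_cost`
#' carried by the line (see [staff_line()]) takes precedence; published cost
#' tables occasionally differ from the formula by a cent or three of source
#' rounding noise, and honouring them keeps site totals reproducible.
#'
#' @param line a one-row [staff_line()] tibble.
#' @param prefer_reported use the line's published cost when present.
#' @return per-clinic cost in A$ (2 decimals).
#' @examples
#' staff_line_cost(staff_line("Orthopedic specialist", 134.57, 0.23, 4, "s"))
#' @export
staff_line_cost <- function(line, prefer_reported = FALSE) {
  if (prefer_reported && !is.na(line$reported_line_cost)) {
    return(line$reported_line_cost)
  }
  round_money(line$hourly_rate * (1 + line$on_cost_fraction) * line$hours_per_clinic)
}

#' Per-clinic staffing cost breakdown for one site
#'
#' Sums [staff_line_cost()] over the staff lines a site bears under a care
#' model. The clinic total is the exact sum of the (already rounded) line
#' costs. A site with no staff lines has a zero total.
#'
#' @param model a [care_model()].
#' @param site_id site within the model.
#' @param prefer_reported prefer published line costs (default `TRUE`, the
#'   reproduction setting).
#' @return list of class `teleroi_clinic_cost`: `site_id`, `lines` (tibble
#'   with a `cost` column) and `clinic_total` (A$).
#' @export
site_clinic_cost <- function(model, site_id, prefer_reported = TRUE) {
  stopifnot(inherits(model, "teleroi_care_model"))
  if (!site_id %in% model$sites$site_id) {
    abort_validation(sprintf("unknown site '%s' in model '%s'", site_id, model$model_id))
  }
  lines <- model$staff_lines[model$staff_lines$site_id == site_id, , drop = FALSE]
  costs <- if (nrow(lines)) {
    vapply(seq_len(nrow(lines)),
           function(i) staff_line_cost(lines[i, ], prefer_reported), 0)
  } else numeric(0)
  lines$cost <- costs
  structure(
    list(site_id = site_id, lines = lines, clinic_total = sum(costs)),
    class = "teleroi_clinic_cost"
  )
}

#' @export
print.teleroi_clinic_cost <- function(x, ...) {
  cat(sprintf("<clinic cost> site %s: A$%.2f per clinic over %d staff line(s)\n",
              x$site_id, x$clinic_total, nrow(x$lines)))
  invisible(x)
}

#' Discount factor for a financial year
#'
#' Returns the schedule's multiplicative factor for `year_label`; the base
#' year always returns exactly 1. Unknown years are an error.
#'
#' @param schedule a [discount_schedule()].
#' @param year_label financial-year label.
#' @return unitless factor.
#' @export
discount_factor <- function(schedule, year_label) {
  stopifnot(inherits(schedule, "teleroi_discount_schedule"))
  if (year_label == schedule$base_year) return(1)
  if (!year_label %in% names(schedule$factor_by_year)) {
    abort_validation(sprintf("year '%s' not in discount schedule%s", year_label,
                             if (is.null(schedule$id)) "" else sprintf(" '%s'", schedule$id)))
  }
  unname(schedule$factor_by_year[[year_label]])
}

#' Annual staffing cost of a site
#'
#' Per-clinic site total x clinics held in the year x the year's discount
#' factor, rounded half-up to whole dollars (the annual reporting precision).
#'
#' @param model a [care_model()].
#' @param site_id site within the model.
#' @param activity one activity-year row (see [activity_year()]).
#' @param schedule a [discount_schedule()].
#' @param prefer_reported passed to [site_clinic_cost()].
#' @return annual cost, whole A$.
#' @export
annual_staff_cost <- function(model, site_id, activity, schedule,
                              prefer_reported = TRUE) {
  stopifnot(nrow(activity) == 1)
  cc <- site_clinic_cost(model, site_id, prefer_reported)
  f <- discount_factor(schedule, activity$year_label)
  round_dollars(cc$clinic_total * activity$clinics_held * f)
}

#' Annual travel-subsidy cost
#'
#' `base_population x uptake_fraction x average_cost_per_claimant x discount
#' factor`, rounded half-up to whole dollars. The base population is all
#' bookings or attended bookings only, per the policy.
#'
#' @param activity one activity-year row.
#' @param policy a [travel_subsidy_policy()].
#' @param schedule a [discount_schedule()].
#' @param uptake_override optional uptake fraction replacing the policy's
#'   (used by sensitivity sweeps).
#' @return annual subsidy outlay, whole A$.
#' @export
travel_subsidy_cost <- function(activity, policy, schedule, uptake_override = NULL) {
  stopifnot(inherits(policy, "teleroi_travel_policy"), nrow(activity) == 1)
  uptake <- policy$uptake_fraction
  if (!is.null(uptake_override)) {
    check_proportion(uptake_override, "uptake_override")
    uptake <- uptake_override
  }
  base <- switch(policy$base_population,
    all_bookings = activity$total_bookings,
    attended_only = activity$total_bookings - activity$fta_count
  )
  f <- discount_factor(schedule, activity$year_label)
  round_dollars(base * uptake * policy$average_cost_per_claimant * f)
}
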