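#' Attended appointments in a year
#'
#' Without an override, the recorded count `total_bookings - fta_count`.
#' With an FTA-rate override (used by sensitivity analysis), the expected
#' attendance `total_bookings * (1 - fta_override)`, kept fractional so the
#' downstream income arithmetic is exactly linear in `1 - fta_override`.
#'
#' @param activity one activity-year row.
#' @param fta_override optional failure-to-attend rate in `[0, 1]`.
#' @return attended count (integer, or fractional under an override).
#' @export
attended_count <- function(activity, fta_override = NULL) {
  stopifnot(nrow(activity) == 1)
  if (is.null(fta_override)) {
    return(activity$total_bookings - activity$fta_count)
  }
  check_proportion(fta_override, "fta_override")
  activity$total_bookings * (1 - fta_override)
}

#' Annual activity-based-funding income of a site
#'
#' Attended appointments times the sum of the per-appointment rates of every
#' funding stream the site claims under the model, rounded half-up to whole
#' dollars. Failed-to-attend appointments yield no income. A site with no
#' income claims earns 0. New/review and adult/pediatric splits do not
#' affect income: the funding classes used here pay the same rate for new
#' and review appointments.
#'
#' @param model a [care_model()].
#' @param site_id site within the model.
#' @param activity one activity-year row.
#' @param streams named list of [funding_stream()] objects.
#' @param fta_override optional FTA rate passed to [attended_count()].
#' @return annual income, whole A$.
#' @export
annual_income <- function(model, site_id, activity, streams, fta_override = NULL) {
  stopifnot(inherits(model, "teleroi_care_model"), nrow(activity) == 1)
  if (!site_id %in% model$sites$site_id) {
    abort_validation(sprintf("unknown site '%s' in model '%s'", site_id, model$model_id))
  }
  claimed <- model$income_claims[[site_id]]
  if (is.null(claimed) || length(claimed) == 0) return(0)
  rate <- sum(vapply(claimed, function(st) {
    stream <- streams[[st]]
    if (is.null(stream)) abort_validation(sprintf("unknown funding stream '%s'", st))
    if (!activity$year_label %in% names(stream$rate_by_year)) {
      abort_validation(sprintf("stream '%s' has no rate for year '%s'",
                               st, activity$year_label))
    }
    stream$rate_by_year[[activity$year_label]]
  }, 0))
  round_dollars(attended_count(activity, fta_override) * rate)
}

#' Calibrate per-appointment funding rates from an income table
#'
#' Inverse problem: published economic evaluations print annual income per
#' site but rarely the per-appointment funding rate behind it. Given the
#' printed income per year and the activity table, the implied rate is
#' `income / attended` for each year. Feeding the calibrated stream back
#' through [annual_income()] reproduces the input incomes to within A$1
#' (whole-dollar rounding).
#'
#' @param income_by_year named numeric vector: financial-year label -> A$.
#' @param activity an [activity_table()] covering those years.
#' @param stream_id,label passed to [funding_stream()].
#' @return a [funding_stream()] with one rate per calibration year.
#' @examples
#' act <- activity_year("2016-2017", 1136, 82, 612, 524, 915, 221, 318)
#' calibrate_funding_rates(c("2016-2017" = 184082), act, "provider")
#' @export
calibrate_funding_rates <- function(income_by_year, activity, stream_id,
                                    label = stream_id) {
  if (is.null(names(income_by_year))) {
    abort_validation("income_by_year must be named by financial-year label")
  }
  rates <- vapply(names(income_by_year), function(yr) {
    inc <- income_by_year[[yr]]
    check_nonneg(inc, sprintf("income for %s", yr))
    att <- attended_count(activity_row(activity, yr))
    if (att == 0) {
      if (inc > 0) {
        abort_validation(sprintf("year '%s' has zero attendance but nonzero income", yr))
      }
      return(0)
    }
    inc / att
  }, 0)
  funding_stream(stream_id, rates, label = label)
}
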