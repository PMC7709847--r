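#' One-way sweep over the failure-to-attend rate
#'
#' Recomputes every (model, site, year) income cell at each FTA rate in
#' `rates`; costs are not touched (clinic counts, and hence staffing costs,
#' are held fixed, as is the configured travel subsidy). Because attendance
#' is kept fractional under an override, income is exactly linear in
#' `1 - rate` up to whole-dollar rounding.
#'
#' @param scen a `teleroi_scenario`.
#' @param rates FTA rates to evaluate, each in `[0, 1]`.
#' @return long tibble: `model_id`, `site_id`, `year_label`, `fta_rate`,
#'   `income` (whole A$).
#' @examples
#' sweep <- fta_sweep(fracture_clinic_scenario(), c(0.10, 0.28, 0.35))
#' @export
fta_sweep <- function(scen, rates = c(0.10, 0.35)) {
  stopifnot(inherits(scen, "teleroi_scenario"))
  for (r in rates) check_proportion(r, "fta rate")
  bind_rows(lapply(scen$models, function(m) {
    bind_rows(lapply(m$sites$site_id, function(sid) {
      bind_rows(lapply(seq_len(nrow(scen$activity)), function(i) {
        act <- scen$activity[i, ]
        tibble(model_id = m$model_id, site_id = sid,
               year_label = act$year_label, fta_rate = rates,
               income = vapply(rates, function(r) {
                 annual_income(m, sid, act, scen$streams, fta_override = r)
               }, 0))
      }))
    }))
  }))
}

#' One-way sweep over travel-subsidy uptake
#'
#' Recomputes the annual travel-subsidy cost at each uptake fraction, plus a
#' multi-year total per uptake (the sum of the rounded annual cells, so the
#' total matches what a year-by-year report adds up to). Subsidy cost is
#' exactly linear in uptake before rounding.
#'
#' @param activity an [activity_table()].
#' @param policy a [travel_subsidy_policy()] (its configured uptake is
#'   ignored in favour of each sweep value).
#' @param uptakes uptake fractions to evaluate, each in `[0, 1]`.
#' @param schedule a [discount_schedule()] for the cost years.
#' @return long tibble: `uptake_fraction`, `year_label`, `cost` (whole A$);
#'   one extra row per uptake with `year_label = "all_years"` carrying the
#'   multi-year total.
#' @export
uptake_sweep <- function(activity, policy, uptakes, schedule) {
  stopifnot(inherits(policy, "teleroi_travel_policy"))
  for (u in uptakes) check_proportion(u, "uptake")
  out <- bind_rows(lapply(uptakes, function(u) {
    yearly <- vapply(seq_len(nrow(activity)), function(i) {
      travel_subsidy_cost(activity[i, ], policy, schedule, uptake_override = u)
    }, 0)
    tibble(uptake_fraction = u,
           year_label = c(activity$year_label, "all_years"),
           cost = c(yearly, sum(yearly)))
  }))
  out
}
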