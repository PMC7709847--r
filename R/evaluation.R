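#' Return on investment
#'
#' `100 * (total_income - total_cost) / total_cost`. Undefined for zero cost:
#' returns `NA_real_` (a distinct "not applicable" signal, never 0), since a
#' site that bore no cost has no investment to return on. Vectorised.
#'
#' @param total_cost,total_income totals in A$; cost must be non-negative.
#' @return ROI in percent, full precision (round for presentation).
#' @examples
#' roi_percent(367390, 485828)   # ~32.2
#' roi_percent(650991, 0)        # -100
#' @export
roi_percent <- function(total_cost, total_income) {
  if (any(total_cost < 0, na.rm = TRUE) || any(total_income < 0, na.rm = TRUE)) {
    abort_validation("costs and incomes must be non-negative")
  }
  ifelse(total_cost > 0, 100 * (total_income - total_cost) / total_cost, NA_real_)
}

#' Breakeven attendance per clinic
#'
#' Smallest whole number of attended appointments `b` whose income covers
#' the per-clinic cost: `b * income_per_attended >= clinic_cost`.
#' Appointments are indivisible, so the answer is a ceiling. When the site
#' earns nothing per appointment but bears a positive cost, breakeven is
#' unreachable and `Inf` is returned. Zero cost needs zero appointments.
#' Vectorised over both arguments.
#'
#' @param clinic_cost per-clinic cost, A$ (non-negative).
#' @param income_per_attended A$ earned per attended appointment.
#' @return integer-valued numeric vector; `Inf` marks unreachable.
#' @examples
#' breakeven_appointments(1341.42, 225.04)  # 6
#' breakeven_appointments(500, 0)           # Inf (cost can never be recouped)
#' @export
breakeven_appointments <- function(clinic_cost, income_per_attended) {
  if (any(clinic_cost < 0) || any(income_per_attended < 0)) {
    abort_validation("clinic_cost and income_per_attended must be non-negative")
  }
  n <- max(length(clinic_cost), length(income_per_attended))
  cost <- rep_len(clinic_cost, n)
  rate <- rep_len(income_per_attended, n)
  out <- numeric(n)
  zero <- cost <= 0
  unreachable <- !zero & rate == 0
  ok <- !zero & !unreachable
  out[zero] <- 0
  out[unreachable] <- Inf
  # relative epsilon: an exact multiple must not be pushed up a whole unit
  out[ok] <- ceiling(cost[ok] / rate[ok] * (1 - 1e-12))
  out
}

#' Run a full scenario evaluation
#'
#' The scenario runner: for every (care model, site, year) it computes the
#' cost cell (staffing plus any travel subsidy borne by the site, each
#' discounted by the model's schedule) and the income cell (activity-based
#' funding for attended appointments), then per (model, site) the multi-year
#' totals, net benefit and ROI. Income is also evaluated at the FTA-rate
#' bounds in `fta_rates` for the standard sensitivity columns; costs are held
#' fixed (clinic counts do not change with attendance).
#'
#' @param scen a `teleroi_scenario` (see [load_scenario()]).
#' @param fta_rates length-2 numeric, the low and high failure-to-attend
#'   rates bounding the income sensitivity interval.
#' @param prefer_reported prefer published staff-line costs (see
#'   [staff_line_cost()]).
#' @return list of class `teleroi_result`: `cells` (one row per model, site,
#'   year: `cost`, `income`, `income_low_fta`, `income_high_fta`) and
#'   `totals` (per model and site: `total_cost`, `total_income`,
#'   `net_benefit`, `roi_percent`; ROI is `NA` where the site bore no cost).
#' @examples
#' res <- run_scenario(fracture_clinic_scenario())
#' res$totals
#' @export
run_scenario <- function(scen, fta_rates = c(0.10, 0.35), prefer_reported = TRUE) {
  stopifnot(inherits(scen, "teleroi_scenario"), length(fta_rates) == 2)
  fta_rates <- sort(fta_rates)
  cells <- bind_rows(lapply(scen$models, function(m) {
    sched <- scen$schedules[[m$discount_schedule_id]]
    bind_rows(lapply(m$sites$site_id, function(sid) {
      bind_rows(lapply(seq_len(nrow(scen$activity)), function(i) {
        act <- scen$activity[i, ]
        cost <- annual_staff_cost(m, sid, act, sched, prefer_reported)
        if (!is.null(m$travel_policy) && m$travel_policy$site_id == sid) {
          cost <- cost + travel_subsidy_cost(act, m$travel_policy$policy, sched)
        }
        tibble(
          model_id = m$model_id, site_id = sid, year_label = act$year_label,
          cost = cost,
          income = annual_income(m, sid, act, scen$streams),
          income_low_fta = annual_income(m, sid, act, scen$streams, fta_rates[1]),
          income_high_fta = annual_income(m, sid, act, scen$streams, fta_rates[2])
        )
      }))
    }))
  }))
  totals <- cells |>
    group_by(.data$model_id, .data$site_id) |>
    summarise(total_cost = sum(.data$cost),
              total_income = sum(.data$income),
              total_income_low_fta = sum(.data$income_low_fta),
              total_income_high_fta = sum(.data$income_high_fta),
              .groups = "drop") |>
    mutate(net_benefit = .data$total_income - .data$total_cost,
           roi_percent = roi_percent(.data$total_cost, .data$total_income))
  structure(
    list(cells = cells, totals = totals, fta_rates = fta_rates,
         years = scen$activity$year_label),
    class = "teleroi_result"
  )
}

#' @export
print.teleroi_result <- function(x, ...) {
  cat(sprintf("<scenario result> %d model-site positions over %s\n",
              nrow(x$totals), paste(x$years, collapse = ", ")))
  cat(sprintf("  income sensitivity at FTA %g%% - %g%%\n",
              100 * x$fta_rates[1], 100 * x$fta_rates[2]))
  df <- as.data.frame(x$totals)
  df$roi_percent <- ifelse(is.na(df$roi_percent), "n/a",
                           sprintf("%.1f", df$roi_percent))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Breakeven attendance table for a scenario
#'
#' For every (model, site): the per-clinic cost (staffing total plus, for a
#' site bearing a travel subsidy, the reference year's subsidy spread over
#' its clinics), the income earned per attended appointment in the reference
#' year (sum of claimed stream rates), and the breakeven attendance from
#' [breakeven_appointments()]. `Inf` in the `breakeven` column means the
#' site cannot recoup its cost at any attendance (no income stream).
#'
#' @param scen a `teleroi_scenario`.
#' @param year_label reference financial year for rates (default: the
#'   scenario's base year).
#' @param prefer_reported see [staff_line_cost()].
#' @return tibble: `model_id`, `site_id`, `clinic_cost`,
#'   `income_per_attended`, `breakeven`.
#' @examples
#' breakeven_table(fracture_clinic_scenario())
#' @export
breakeven_table <- function(scen, year_label = scen$base_year,
                            prefer_reported = TRUE) {
  stopifnot(inherits(scen, "teleroi_scenario"))
  act <- activity_row(scen$activity, year_label)
  bind_rows(lapply(scen$models, function(m) {
    sched <- scen$schedules[[m$discount_schedule_id]]
    bind_rows(lapply(m$sites$site_id, function(sid) {
      cost <- site_clinic_cost(m, sid, prefer_reported)$clinic_total
      if (!is.null(m$travel_policy) && m$travel_policy$site_id == sid &&
          act$clinics_held > 0) {
        cost <- cost + travel_subsidy_cost(act, m$travel_policy$policy, sched) /
          act$clinics_held
      }
      claimed <- m$income_claims[[sid]]
      rate <- if (is.null(claimed)) 0 else {
        sum(vapply(claimed, function(st) scen$streams[[st]]$rate_by_year[[year_label]], 0))
      }
      tibble(model_id = m$model_id, site_id = sid,
             clinic_cost = round_money(cost), income_per_attended = rate,
             breakeven = breakeven_appointments(cost, rate))
    }))
  }))
}
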