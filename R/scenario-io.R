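#' Load a scenario configuration document
#'
#' Reads a YAML scenario document (schema version 1), builds all domain
#' objects and cross-validates them. Errors carry a path into the document
#' (e.g. `care_models[travel].staff_lines: ...`). Loading is deterministic:
#' identical documents produce identical scenarios.
#'
#' @param path path to a YAML scenario document.
#' @return a validated `teleroi_scenario` (see [scenario()]).
#' @seealso [write_scenario()], [fracture_clinic_scenario()] for the bundled
#'   orthopedic fracture-clinic case study.
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) abort_validation(sprintf("no such file: %s", path))
  doc <- yaml::read_yaml(path)
  scenario_from_list(doc)
}

# build a scenario from a parsed document (list) -- shared by load/round-trip
scenario_from_list <- function(doc) {
  ver <- doc$schema_version
  if (is.null(ver)) abort_validation("missing schema_version", "schema_version")
  if (!identical(as.integer(ver), 1L)) {
    abort_validation(sprintf("unsupported schema_version %s (supported: 1)", ver),
                     "schema_version")
  }
  if (is.null(doc$activity) || length(doc$activity) == 0) {
    abort_validation("at least one activity year is required", "activity")
  }
  activity <- bind_rows(lapply(doc$activity, function(a) {
    need <- c("financial_year", "total_bookings", "clinics_held", "new_bookings",
              "review_bookings", "adult_bookings", "pediatric_bookings")
    miss <- setdiff(need, names(a))
    if (length(miss)) {
      abort_validation(sprintf("missing field '%s'", miss[1]),
                       sprintf("activity[%s]", a$financial_year %||% "?"))
    }
    fta <- resolve_fta(a, path = sprintf("activity[%s]", a$financial_year))
    activity_year(a$financial_year, a$total_bookings, a$clinics_held,
                  a$new_bookings, a$review_bookings,
                  a$adult_bookings, a$pediatric_bookings, fta)
  }))
  activity <- activity_table(activity)

  streams <- lapply(doc$funding_streams, function(s) {
    if (is.null(s$stream_id)) abort_validation("missing stream_id", "funding_streams")
    funding_stream(s$stream_id, unlist(s$rates), label = s$label %||% s$stream_id)
  })

  schedules <- lapply(names(doc$discount_schedules), function(id) {
    d <- doc$discount_schedules[[id]]
    discount_schedule(
      base_year = d$base_year %||% abort_validation("missing base_year",
                                                    sprintf("discount_schedules[%s]", id)),
      factor_by_year = if (!is.null(d$factors)) unlist(d$factors),
      periods_back = if (!is.null(d$periods_back)) unlist(d$periods_back),
      annual_rate = d$annual_rate %||% 0.025,
      id = id)
  })

  allowed_oncosts <- doc$allowed_on_cost_fractions
  if (!length(allowed_oncosts)) allowed_oncosts <- NULL
  models <- lapply(doc$care_models, function(m) {
    path <- sprintf("care_models[%s]", m$model_id %||% "?")
    if (is.null(m$model_id)) abort_validation("missing model_id", "care_models")
    sites <- bind_rows(lapply(m$sites, as_tibble))
    lines <- if (length(m$staff_lines)) {
      bind_rows(lapply(seq_along(m$staff_lines), function(i) {
        l <- m$staff_lines[[i]]
        lpath <- sprintf("%s.staff_lines[%d]", path, i)
        if (!is.null(allowed_oncosts) && is.null(l$on_cost_override) &&
            !any(abs(l$on_cost_fraction - unlist(allowed_oncosts)) < 1e-12)) {
          abort_validation(sprintf(
            "on_cost_fraction %g is not one of the configured values (%s); set on_cost_override: true to allow",
            l$on_cost_fraction, paste(allowed_oncosts, collapse = ", ")), lpath)
        }
        staff_line(l$role_name, l$hourly_rate, l$on_cost_fraction,
                   l$hours_per_clinic, l$site_id,
                   reported_line_cost = l$line_cost)
      }))
    } else NULL
    policy <- if (!is.null(m$travel_policy)) {
      tp <- m$travel_policy
      list(site_id = tp$site_id,
           policy = travel_subsidy_policy(tp$uptake_fraction,
                                          tp$average_cost_per_claimant,
                                          tp$base_population %||% "all_bookings"))
    }
    care_model(m$model_id, sites, lines,
               income_claims = m$income_claims %||% list(),
               travel_policy = policy,
               discount_schedule_id = m$discount_schedule %||% "staffing",
               label = m$label %||% m$model_id)
  })

  scen <- scenario(models, activity, streams, schedules,
                   base_year = doc$base_year, schema_version = ver)
  scen$allowed_on_cost_fractions <- if (!is.null(allowed_oncosts)) unlist(allowed_oncosts)
  scen$description <- doc$description
  scen
}

# FTA may be given as a count or a rate; the count wins when both appear;
# a rate converts to a count by half-up rounding.
resolve_fta <- function(a, path) {
  if (!is.null(a$fta_count)) return(a$fta_count)
  if (!is.null(a$fta_rate)) {
    check_proportion(a$fta_rate, "fta_rate", path)
    return(round_half_up(a$fta_rate * a$total_bookings))
  }
  abort_validation("one of fta_count or fta_rate is required", path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a scenario back to a YAML document
#'
#' The written document reloads to an identical scenario (numeric factors
#' and rates are serialised at 15 significant digits).
#'
#' @param scen a `teleroi_scenario`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(scen, path) {
  stopifnot(inherits(scen, "teleroi_scenario"))
  doc <- list(
    schema_version = scen$schema_version,
    description = scen$description,
    base_year = scen$base_year,
    allowed_on_cost_fractions = if (length(scen$allowed_on_cost_fractions)) {
      as.list(scen$allowed_on_cost_fractions)
    },
    activity = lapply(seq_len(nrow(scen$activity)), function(i) {
      r <- scen$activity[i, ]
      list(financial_year = r$year_label, total_bookings = r$total_bookings,
           clinics_held = r$clinics_held, new_bookings = r$new_bookings,
           review_bookings = r$review_bookings, adult_bookings = r$adult_bookings,
           pediatric_bookings = r$pediatric_bookings, fta_count = r$fta_count)
    }),
    funding_streams = lapply(unname(scen$streams), function(s) {
      list(stream_id = s$stream_id, label = s$label,
           rates = as.list(s$rate_by_year))
    }),
    discount_schedules = lapply(scen$schedules, function(d) {
      list(base_year = d$base_year, factors = as.list(d$factor_by_year))
    }),
    care_models = lapply(unname(scen$models), function(m) {
      out <- list(
        model_id = m$model_id, label = m$label,
        discount_schedule = m$discount_schedule_id,
        sites = lapply(seq_len(nrow(m$sites)), function(i) as.list(m$sites[i, ])),
        staff_lines = lapply(seq_len(nrow(m$staff_lines)), function(i) {
          l <- as.list(m$staff_lines[i, ])
          if (is.na(l$reported_line_cost)) l$reported_line_cost <- NULL
          names(l)[names(l) == "reported_line_cost"] <- "line_cost"
          l
        }),
        income_claims = lapply(m$income_claims, as.list)
      )
      if (!is.null(m$travel_policy)) {
        out$travel_policy <- list(
          site_id = m$travel_policy$site_id,
          uptake_fraction = m$travel_policy$policy$uptake_fraction,
          average_cost_per_claimant = m$travel_policy$policy$average_cost_per_claimant,
          base_population = m$travel_policy$policy$base_population)
      }
      out
    })
  )
  doc <- Filter(Negate(is.null), doc)
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

#' Read / write activity tables as CSV
#'
#' Columns mirror the standard activity-report headings: `financial_year`,
#' `total_bookings`, `clinics_held`, `new_bookings`, `review_bookings`,
#' `adult_bookings`, `pediatric_bookings`, `fta_count`. Writing then reading
#' is lossless.
#'
#' @param activity an [activity_table()].
#' @param path CSV file path.
#' @return `read_activity_table` returns a validated activity table;
#'   `write_activity_table` returns `path` invisibly.
#' @export
write_activity_table <- function(activity, path) {
  if (is.null(activity) || nrow(activity) == 0) {
    abort_validation("activity table must have at least one year", "activity")
  }
  out <- as.data.frame(activity)
  names(out)[names(out) == "year_label"] <- "financial_year"
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_activity_table
#' @export
read_activity_table <- function(path) {
  if (!file.exists(path)) abort_validation(sprintf("no such file: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE)
  names(df)[names(df) == "financial_year"] <- "year_label"
  activity_table(as.data.frame(df))
}
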