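#' Configuration for the synthetic activity generator
#'
#' The generator emulates the structure of an aggregate outpatient activity
#' report: per year, a clinic count, a booking volume built up per clinic,
#' and binomial failure-to-attend and patient-mix splits. Defaults are set
#' to the scale of a busy telehealth fracture clinic (about 82 clinics a
#' year of ~14 bookings each with 28% failure to attend, a 54/46 new/review
#' mix and 19% pediatric patients).
#'
#' @param n_years number of financial years to generate.
#' @param clinics_per_year_mean mean clinics per year (Poisson, zero-clinic
#'   years rejected).
#' @param bookings_per_clinic_mean mean bookings per clinic (Poisson per
#'   clinic, summed).
#' @param fta_probability per-booking failure-to-attend probability.
#' @param new_fraction per-booking probability of being a new (vs review)
#'   appointment.
#' @param pediatric_fraction per-booking probability of being pediatric.
#' @param seed integer seed; the same seed always yields the same table.
#' @param first_year first calendar year of the first financial-year label
#'   (labels are generated as `"2014-2015"`, `"2015-2016"`, ...).
#' @return list of class `teleroi_generator_config`.
#' @export
activity_generator_config <- function(n_years = 3,
                                      clinics_per_year_mean = 82,
                                      bookings_per_clinic_mean = 13.9,
                                      fta_probability = 0.28,
                                      new_fraction = 0.54,
                                      pediatric_fraction = 0.19,
                                      seed = 1L,
                                      first_year = 2014L) {
  check_nonneg(n_years, "n_years")
  if (n_years < 1) abort_validation("n_years must be at least 1")
  if (clinics_per_year_mean <= 0) abort_validation("clinics_per_year_mean must be > 0")
  if (bookings_per_clinic_mean <= 0) abort_validation("bookings_per_clinic_mean must be > 0")
  check_proportion(fta_probability, "fta_probability")
  check_proportion(new_fraction, "new_fraction")
  check_proportion(pediatric_fraction, "pediatric_fraction")
  structure(
    list(n_years = as.integer(n_years),
         clinics_per_year_mean = clinics_per_year_mean,
         bookings_per_clinic_mean = bookings_per_clinic_mean,
         fta_probability = fta_probability,
         new_fraction = new_fraction,
         pediatric_fraction = pediatric_fraction,
         seed = as.integer(seed),
         first_year = as.integer(first_year)),
    class = "teleroi_generator_config"
  )
}

#' Generate a synthetic activity table
#'
#' Draws, for each year: a clinic count from Poisson(`clinics_per_year_mean`)
#' with zero-clinic years rejected; a booking total as the sum of one
#' Poisson(`bookings_per_clinic_mean`) draw per clinic; and binomial
#' failure-to-attend, new/review and adult/pediatric splits over the
#' bookings. Every generated table satisfies the [activity_year()]
#' invariants by construction. The generator uses (and then restores) R's
#' global RNG stream, seeded from `config$seed`, so output is reproducible.
#'
#' @param config an [activity_generator_config()].
#' @return an [activity_table()] with `config$n_years` rows.
#' @examples
#' generate_activity(activity_generator_config(seed = 42))
#' @export
generate_activity <- function(config) {
  stopifnot(inherits(config, "teleroi_generator_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(config$seed)
  rows <- lapply(seq_len(config$n_years), function(i) {
    clinics <- 0L
    while (clinics == 0L) clinics <- rpois(1, config$clinics_per_year_mean)
    bookings <- sum(rpois(clinics, config$bookings_per_clinic_mean))
    fta <- rbinom(1, bookings, config$fta_probability)
    new <- rbinom(1, bookings, config$new_fraction)
    pediatric <- rbinom(1, bookings, config$pediatric_fraction)
    activity_year(
      year_label = sprintf("%d-%d", config$first_year + i - 1L, config$first_year + i),
      total_bookings = bookings, clinics_held = clinics,
      new_bookings = new, review_bookings = bookings - new,
      adult_bookings = bookings - pediatric, pediatric_bookings = pediatric,
      fta_count = fta)
  })
  activity_table(bind_rows(rows))
}
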