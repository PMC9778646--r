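#' Configuration for the synthetic surveillance generator
#'
#' Bundles every parameter of the simulated sampling design: the
#' three-season Monday/Wednesday/Friday schedule, the butcher shift
#' rotation, cold-chain temperatures, and per-analyte count models of the
#' form
#' \deqn{count = baseline + butcher_effect + weekday_effect +
#'       slope (meat\_temp - 4) + N(0, \sigma)}
#' clipped to the `count_clip` range. Defaults are calibrated so that the
#' default 216-sample dataset reproduces the class marginals of the routine
#' surveillance summary (MAB roughly 33/27/40 percent
#' satisfactory/acceptable/unsatisfactory, E. coli 95/5/0, S. aureus
#' 94/4/2), a Salmonella prevalence of 6.9 percent, and a LAB histogram with
#' modal bins 2-4 and 4-6 log10 CFU/g.
#'
#' @param years Sampling years; default `2019:2021`.
#' @param weeks_per_year Weeks sampled per year; default 24, giving
#'   3 x 24 x 3 = 216 sampling events.
#' @param weekdays Sampling weekdays; default Monday, Wednesday, Friday.
#' @param rotation Butcher shift rotation pattern, cycled over events;
#'   default a plain A-B-C-D cycle.
#' @param storage_mean,storage_sd Storage temperature distribution (degrees
#'   Celsius) before clipping.
#' @param storage_clip Closed clip interval for storage temperature;
#'   default `c(2, 7)`, the cold-chain range.
#' @param offset_mean,offset_sd Meat-minus-storage temperature offset
#'   distribution, clipped below at 0 so meat is never colder than storage.
#' @param analytes Named list (`mab`, `lab`, `e_coli`, `s_aureus`), each a
#'   list with `baseline`, `sd`, `butcher` (named effects for A-D),
#'   `weekday` (named effects) and `temp_slope` (per degree of meat
#'   temperature above 4).
#' @param salmonella_prevalence Per-sample Bernoulli probability of a
#'   Salmonella-positive result; default 0.069.
#' @param count_clip Clip interval for counts in log10 CFU/g; default
#'   `c(0, 9)`.
#' @param seed Integer seed used by [generate_dataset()]; `NULL` leaves the
#'   RNG state untouched.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(years = 2019:2021,
                             weeks_per_year = 24,
                             weekdays = c("Monday", "Wednesday", "Friday"),
                             rotation = c("A", "B", "C", "D"),
                             storage_mean = 4, storage_sd = 1,
                             storage_clip = c(2, 7),
                             offset_mean = 1.5, offset_sd = 0.8,
                             analytes = default_analyte_params(),
                             salmonella_prevalence = 0.069,
                             count_clip = c(0, 9),
                             seed = NULL) {
  if (salmonella_prevalence < 0 || salmonella_prevalence > 1) {
    abort("salmonella_prevalence must lie in [0, 1]")
  }
  sds <- c(storage_sd, offset_sd, purrr::map_dbl(analytes, "sd"))
  if (any(sds < 0)) abort("standard deviations must be non-negative")
  structure(
    list(years = years, weeks_per_year = weeks_per_year, weekdays = weekdays,
         rotation = rotation, storage_mean = storage_mean,
         storage_sd = storage_sd, storage_clip = storage_clip,
         offset_mean = offset_mean, offset_sd = offset_sd,
         analytes = analytes, salmonella_prevalence = salmonella_prevalence,
         count_clip = count_clip, seed = seed),
    class = "generator_config"
  )
}

#' @rdname generator_config
#' @export
default_analyte_params <- function() {
  list(
    mab = list(baseline = 5.07, sd = 0.70,
               butcher = c(A = 0.2, B = -2.1, C = 1.2, D = 0.7),
               weekday = c(Monday = -0.2, Wednesday = 0.1, Friday = -0.1),
               temp_slope = 0.25),
    lab = list(baseline = 4.36, sd = 0.96,
               butcher = c(A = 0.35, B = 0.1, C = -0.7, D = 0.7),
               weekday = c(Monday = -0.3, Wednesday = 1.2, Friday = -0.35),
               temp_slope = -0.40),
    e_coli = list(baseline = 0.74, sd = 0.44,
                  butcher = c(A = 0.15, B = -0.75, C = 0.55, D = -0.25),
                  weekday = c(Monday = -0.05, Wednesday = -0.15,
                              Friday = 0.1),
                  temp_slope = 0.15),
    s_aureus = list(baseline = -1.97, sd = 2.10,
                    butcher = c(A = -0.9, B = -0.4, C = 0.7, D = 1.2),
                    weekday = c(Monday = 0.1, Wednesday = -0.1,
                                Friday = 0.15),
                    temp_slope = 0.15)
  )
}

#' Build the deterministic sampling schedule
#'
#' One sampling event per (year, week, weekday) combination, ordered by
#' year, then week, then the order weekdays are given.
#'
#' @param years Vector of years (non-empty).
#' @param weeks_per_year Number of sampled weeks per year (>= 1).
#' @param weekdays Character vector of sampling weekdays (non-empty).
#' @return A tibble with columns `year`, `week_index`, `weekday` and
#'   `length(years) * weeks_per_year * length(weekdays)` rows.
#' @export
#' @examples
#' nrow(build_schedule(2019:2021, 24, c("Monday", "Wednesday", "Friday")))
build_schedule <- function(years, weeks_per_year, weekdays) {
  if (length(years) == 0) abort("years must be non-empty")
  if (weeks_per_year < 1) abort("weeks_per_year must be at least 1")
  if (length(weekdays) == 0) abort("weekdays must be non-empty")
  tidyr::expand_grid(
    year = as.integer(years),
    week_index = seq_len(weeks_per_year),
    weekday = weekdays
  )
}

#' Assign butchers to the schedule by shift rotation
#'
#' The four butchers work continuous shifts; the rotation pattern is cycled
#' deterministically over sampling events in schedule order.
#'
#' @param schedule Schedule tibble from [build_schedule()].
#' @param rotation Non-empty character vector over `A`-`D`.
#' @return The schedule with a `butcher` column appended.
#' @export
assign_butchers <- function(schedule, rotation = c("A", "B", "C", "D")) {
  if (length(rotation) == 0) abort("rotation must be non-empty")
  bad <- setdiff(rotation, c("A", "B", "C", "D"))
  if (length(bad) > 0) {
    abort(paste0("unknown butcher symbol(s): ", paste(bad, collapse = ", ")))
  }
  dplyr::mutate(schedule,
                butcher = rep_len(rotation, nrow(schedule)))
}

clip <- function(x, bounds) pmin(pmax(x, bounds[1]), bounds[2])

#' Draw cold-chain temperatures
#'
#' Storage temperature is Gaussian, clipped to the configured cold-chain
#' interval; meat temperature is storage plus a non-negative Gaussian
#' offset (meat arrives no colder than its storage environment). Draws use
#' the current RNG state; seed upstream (e.g. via [generate_dataset()]) for
#' reproducibility.
#'
#' @param schedule Schedule tibble (any table; one draw per row).
#' @param config A [generator_config()].
#' @return The schedule with `storage_temp` and `meat_temp` columns.
#' @export
draw_temperatures <- function(schedule, config = generator_config()) {
  n <- nrow(schedule)
  storage <- clip(rnorm(n, config$storage_mean, config$storage_sd),
                  config$storage_clip)
  offset <- pmax(rnorm(n, config$offset_mean, config$offset_sd), 0)
  dplyr::mutate(schedule,
                storage_temp = storage,
                meat_temp = storage + offset)
}

#' Draw the microbial profile for each sampling event
#'
#' Adds the four count columns (`mab`, `lab`, `e_coli`, `s_aureus`, log10
#' CFU/g, clipped to the configured range) and the two presence flags.
#' Counts follow the additive model documented in [generator_config()];
#' Salmonella positivity is Bernoulli with the configured prevalence and
#' L. monocytogenes is never detected under defaults.
#'
#' @param records Table with `butcher`, `weekday` and `meat_temp` columns.
#' @param config A [generator_config()].
#' @return `records` with the six microbial columns appended.
#' @export
draw_microbial_profile <- function(records, config = generator_config()) {
  n <- nrow(records)
  draw_one <- function(p) {
    x <- p$baseline +
      unname(p$butcher[records$butcher]) +
      unname(p$weekday[records$weekday]) +
      p$temp_slope * (records$meat_temp - 4) +
      rnorm(n, 0, p$sd)
    clip(x, config$count_clip)
  }
  dplyr::mutate(records,
                mab = draw_one(config$analytes$mab),
                lab = draw_one(config$analytes$lab),
                e_coli = draw_one(config$analytes$e_coli),
                s_aureus = draw_one(config$analytes$s_aureus),
                salmonella_present = runif(n) < config$salmonella_prevalence,
                l_mono_present = FALSE)
}

dataset_columns <- function() {
  c("sample_id", "year", "week_index", "weekday", "butcher",
    "storage_temp", "meat_temp", "mab", "lab", "e_coli", "s_aureus",
    "salmonella_present", "l_mono_present")
}

#' Generate a synthetic surveillance dataset
#'
#' Composes [build_schedule()], [assign_butchers()], [draw_temperatures()]
#' and [draw_microbial_profile()] under one seed. The default configuration
#' yields 216 records (3 years x 24 weeks x 3 weekdays) with 13 columns.
#'
#' @param config A [generator_config()]; its `seed` element, when not
#'   `NULL`, seeds the RNG before any draw.
#' @return A tibble of sample records, one per sampling event.
#' @export
#' @examples
#' d <- generate_dataset(generator_config(seed = 1))
#' dim(d)
generate_dataset <- function(config = generator_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  build_schedule(config$years, config$weeks_per_year, config$weekdays) |>
    assign_butchers(config$rotation) |>
    draw_temperatures(config) |>
    draw_microbial_profile(config) |>
    dplyr::mutate(sample_id = dplyr::row_number()) |>
    dplyr::select(dplyr::all_of(dataset_columns()))
}

#' Read and write sample tables as CSV
#'
#' Plain CSV with a header row and the fixed column set of
#' [generate_dataset()]. `write_dataset()` writes doubles at full precision
#' so a write/read round trip reproduces the table exactly.
#'
#' @param records Sample table.
#' @param path CSV file path.
#' @return `read_dataset()` returns the sample tibble; `write_dataset()`
#'   returns `path` invisibly.
#' @export
write_dataset <- function(records, path) {
  readr::write_csv(records, path)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) abort(paste0("dataset file not found: ", path))
  readr::read_csv(path, col_types = readr::cols(
    sample_id = readr::col_integer(),
    year = readr::col_integer(),
    week_index = readr::col_integer(),
    weekday = readr::col_character(),
    butcher = readr::col_character(),
    storage_temp = readr::col_double(),
    meat_temp = readr::col_double(),
    mab = readr::col_double(),
    lab = readr::col_double(),
    e_coli = readr::col_double(),
    s_aureus = readr::col_double(),
    salmonella_present = readr::col_logical(),
    l_mono_present = readr::col_logical()
  ))
}
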