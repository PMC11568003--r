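# Synthetic Gompertz-style inputs. Hip fracture incidence and adult mortality
# both rise roughly exponentially with age; these generators produce banded
# tables with that structure so the whole pipeline is exercisable without any
# external national data. Parameters of the canonical fixtures mirror the
# qualitative situation the pipeline is built for: a donor country with lower
# old-age mortality than the index country, female hip incidence about twice
# the male, and a growing, ageing population.

#' Gompertz-style rate parameters
#'
#' @param rate_at_50 rate at age 50 (in the table's unit; positive).
#' @param log_slope exponential increase per year of age (in [0, 0.25]).
#' @param sex_ratio female:male multiplier (positive; hip incidence is
#'   typically ~2, mortality typically < 1).
#' @return A \code{gompertz_params} list.
#' @export
gompertz_params <- function(rate_at_50, log_slope, sex_ratio = 1) {
  if (rate_at_50 <= 0) value_error("rate_at_50 must be positive")
  if (log_slope < 0 || log_slope > 0.25) {
    value_error("log_slope must lie in [0, 0.25]")
  }
  if (sex_ratio <= 0) value_error("sex_ratio must be positive")
  structure(list(rate_at_50 = rate_at_50, log_slope = log_slope,
                 sex_ratio = sex_ratio), class = "gompertz_params")
}

#' Generate a banded rate table from Gompertz parameters
#'
#' The male rate of each band is \code{rate_at_50 * exp(log_slope *
#' (band_midpoint - 50))}; the female rate is the male rate times
#' \code{sex_ratio}. The last band is open-ended (its nominal midpoint is
#' \code{start + band_width/2}). Deterministic unless band-level jitter is
#' requested: with \code{jitter_sd > 0}, each band's rate is multiplied by an
#' independent log-normal factor (reproducible given \code{seed}).
#'
#' @param params a \code{gompertz_params}.
#' @param band_width band width in years (default 5).
#' @param age_range closed start / open end of the banded range (default
#'   \code{c(50, 90)}; a final open-ended band starting at \code{age_range[2]}
#'   is appended).
#' @param unit rate unit of the output table.
#' @param label table label.
#' @param jitter_sd SD of log-normal band jitter (default 0 = off).
#' @param seed RNG seed, used only when \code{jitter_sd > 0}.
#' @return A \code{rate_table}.
#' @export
gompertz_rate_table <- function(params, band_width = 5, age_range = c(50, 90),
                                unit = c("per_100k", "per_person_year"),
                                label = "synthetic Gompertz rates",
                                jitter_sd = 0, seed = 1L) {
  unit <- match.arg(unit)
  stopifnot(inherits(params, "gompertz_params"))
  starts <- seq(age_range[1], age_range[2], by = band_width)
  ends <- c(starts[-1], Inf)
  mids <- starts + band_width / 2
  male <- params$rate_at_50 * exp(params$log_slope * (mids - 50))
  rates <- c(male, male * params$sex_ratio)
  if (jitter_sd > 0) {
    set.seed(seed)
    rates <- rates * exp(stats::rnorm(length(rates), 0, jitter_sd))
  }
  rate_table(data.frame(sex = rep(c("male", "female"), each = length(starts)),
                        age_start = rep(starts, 2), age_end = rep(ends, 2),
                        rate = rates),
             unit = unit, label = label)
}

#' Default MOF:hip ratio fixture
#'
#' A synthetic ratio table shaped like the published reference pattern: the
#' MOF:hip incidence ratio falls with age, from roughly 6 at age 50 to 2 from
#' age 85 on, identically for both sexes. It is a stand-in with the right
#' structure, not the published values.
#'
#' @return A \code{ratio_table} covering ages 50 and above.
#' @export
default_mof_ratios <- function() {
  starts <- seq(50, 85, by = 5)
  ends <- c(starts[-1], Inf)
  ratios <- c(6.0, 5.2, 4.5, 3.9, 3.3, 2.8, 2.3, 2.0)
  ratio_table(data.frame(sex = rep(c("male", "female"), each = length(starts)),
                         age_start = rep(starts, 2), age_end = rep(ends, 2),
                         ratio = rep(ratios, 2)),
              label = "synthetic reference MOF:hip pattern")
}

#' Canonical donor / surrogate model pair
#'
#' Builds two fracture-probability models sharing the same (donor) hip and
#' imputed MOF incidence and the same risk coefficients, differing only in
#' mortality: the donor model uses the donor country's mortality and the
#' surrogate model the index country's. The canonical defaults make the index
#' country's old-age mortality roughly 1.5-2 times the donor's, so surrogate
#' probabilities fall below donor probabilities at older ages.
#'
#' @param donor_params Gompertz parameters of donor hip incidence (per 100k).
#' @param index_mortality_params Gompertz parameters of index-country annual
#'   mortality hazard (per person-year).
#' @param donor_mortality_params Gompertz parameters of donor-country annual
#'   mortality hazard.
#' @param risk_model shared \code{risk_factor_model}.
#' @param jitter_sd band-level log-normal jitter SD (default 0 = deterministic).
#' @param seed seed controlling the jitter (ignored when \code{jitter_sd} is 0).
#' @return List with elements \code{donor} and \code{surrogate}
#'   (\code{frax_model} each) plus the shared \code{ratios}.
#' @export
make_country_pair <- function(
    donor_params = gompertz_params(15, 0.11, sex_ratio = 2),
    index_mortality_params = gompertz_params(0.0045, 0.098, sex_ratio = 0.55),
    donor_mortality_params = gompertz_params(0.003, 0.095, sex_ratio = 0.55),
    risk_model = risk_factor_model(),
    jitter_sd = 0, seed = 1L) {
  hip <- gompertz_rate_table(donor_params, unit = "per_100k",
                             label = "synthetic donor hip incidence",
                             jitter_sd = jitter_sd, seed = seed)
  mort_index <- gompertz_rate_table(index_mortality_params,
                                    unit = "per_person_year",
                                    label = "synthetic index mortality",
                                    jitter_sd = jitter_sd, seed = seed + 1L)
  mort_donor <- gompertz_rate_table(donor_mortality_params,
                                    unit = "per_person_year",
                                    label = "synthetic donor mortality",
                                    jitter_sd = jitter_sd, seed = seed + 2L)
  ratios <- default_mof_ratios()
  list(
    donor = assemble_surrogate(hip, mort_donor, ratios, risk_model,
                               label = "donor (authentic) model"),
    surrogate = assemble_surrogate(hip, mort_index, ratios, risk_model,
                                   label = "surrogate (index mortality) model"),
    ratios = ratios)
}

#' Deterministic growing, ageing population pyramids
#'
#' Counts grow geometrically: a band with baseline count \eqn{c} and growth
#' fraction \eqn{g} per decade holds \eqn{c (1+g)^{(y - y_0)/10}} persons in
#' year \eqn{y}. Supplying larger growth fractions for older bands mimics an
#' ageing population.
#'
#' @param base_counts data.frame with columns \code{sex}, \code{age_start},
#'   \code{age_end}, \code{count}: the baseline-year pyramid.
#' @param growth_per_decade single fraction, or numeric vector with one entry
#'   per row of \code{base_counts} (>= 0).
#' @param years calendar years to generate; the first is the baseline.
#' @return Named list of \code{population_pyramid}, keyed by year.
#' @export
growing_pyramids <- function(base_counts, growth_per_decade, years) {
  if (any(growth_per_decade < 0)) value_error("growth_per_decade must be >= 0")
  g <- rep(growth_per_decade, length.out = nrow(base_counts))
  base_year <- years[1]
  out <- lapply(years, function(y) {
    counts <- base_counts$count * (1 + g) ^ ((y - base_year) / 10)
    population_pyramid(y, data.frame(sex = base_counts$sex,
                                     age_start = base_counts$age_start,
                                     age_end = base_counts$age_end,
                                     count = counts))
  })
  names(out) <- as.character(years)
  out
}

#' Canonical baseline pyramid for the synthetic index country
#'
#' A young, bottom-heavy pyramid over ages 50+ (the model's domain), with
#' per-band growth fractions rising with age so that projections age as well
#' as grow.
#'
#' @return List with \code{base_counts} (data.frame) and
#'   \code{growth_per_decade} (numeric vector aligned with its rows).
#' @export
canonical_pyramid_spec <- function() {
  starts <- seq(50, 85, by = 5)
  ends <- c(starts[-1], Inf)
  male <- c(600e3, 480e3, 360e3, 250e3, 160e3, 90e3, 45e3, 18e3)
  female <- c(620e3, 500e3, 380e3, 270e3, 180e3, 105e3, 55e3, 24e3)
  base_counts <- data.frame(
    sex = rep(c("male", "female"), each = length(starts)),
    age_start = rep(starts, 2), age_end = rep(ends, 2),
    count = c(male, female))
  growth <- rep(c(0.25, 0.30, 0.35, 0.42, 0.50, 0.58, 0.66, 0.75), 2)
  list(base_counts = base_counts, growth_per_decade = growth)
}

#' @export
print.gompertz_params <- function(x, ...) {
  cat(sprintf("gompertz_params: rate at 50 = %g, log slope = %g/yr, female:male = %g\n",
              x$rate_at_50, x$log_slope, x$sex_ratio))
  invisible(x)
}
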