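#' Yearly hazard paths over a fixed horizon
#'
#' A \code{hazard_path} pairs one fracture hazard and one death hazard per
#' year of the horizon (per person-year, piecewise constant within years).
#' It is the sole input to the probability engine.
#'
#' @param fracture numeric vector of yearly fracture hazards (>= 0).
#' @param death numeric vector of yearly death hazards (>= 0), same length.
#' @return A \code{hazard_path}.
#' @export
hazard_path <- function(fracture, death) {
  if (length(fracture) != length(death)) {
    value_error("fracture and death hazard sequences must have the same length")
  }
  if (length(fracture) == 0) value_error("hazard path must cover at least one year")
  if (any(!is.finite(fracture)) || any(!is.finite(death))) {
    domain_error("hazards must be finite")
  }
  if (any(fracture < 0) || any(death < 0)) domain_error("hazards must be non-negative")
  structure(list(fracture = as.numeric(fracture), death = as.numeric(death),
                 horizon = length(fracture)),
            class = "hazard_path")
}

#' 10-year (horizon) first-fracture probability under competing death
#'
#' Computes the cause-specific cumulative incidence of a first fracture over
#' the path's horizon, with both hazards piecewise constant within years.
#' Over year \eqn{i} with fracture hazard \eqn{f_i} and death hazard
#' \eqn{d_i}, the year contributes
#' \deqn{S_{i-1} \cdot \frac{f_i}{f_i + d_i} \left(1 - e^{-(f_i + d_i)}\right)}
#' where \eqn{S_{i-1} = \exp(-\sum_{j<i}(f_j+d_j))} is the probability of
#' being alive and fracture-free at the start of year \eqn{i} (\eqn{S_0 = 1}).
#' The \eqn{f_i/(f_i+d_i)} factor is the exact probability that the fracture
#' wins the within-year exponential race against death. A year with
#' \eqn{f_i + d_i = 0} contributes zero and leaves \eqn{S} unchanged (the
#' analytic limit). Competing death can only lower the result: it is bounded
#' above by \eqn{1 - \exp(-\sum f_i)}.
#'
#' @param path a \code{hazard_path}.
#' @return Probability in [0, 1] of a first fracture before death within the
#'   horizon.
#' @seealso [monte_carlo_probability()] for the simulation oracle,
#'   [survival_curve()] for the event-free survival sequence.
#' @export
ten_year_probability <- function(path) {
  stopifnot(inherits(path, "hazard_path"))
  f <- path$fracture
  d <- path$death
  h <- f + d
  S <- 1
  total <- 0
  for (i in seq_along(f)) {
    if (h[i] > 0) {
      total <- total + S * (f[i] / h[i]) * (1 - exp(-h[i]))
      S <- S * exp(-h[i])
    }
  }
  total
}

#' Event-free survival curve of a hazard path
#'
#' @param path a \code{hazard_path}.
#' @return Numeric vector of length \code{horizon + 1}:
#'   \eqn{S_i = \exp(-\sum_{j \le i}(f_j + d_j))} with \eqn{S_0 = 1}.
#' @export
survival_curve <- function(path) {
  stopifnot(inherits(path, "hazard_path"))
  c(1, exp(-cumsum(path$fracture + path$death)))
}

#' Build a hazard path from incidence and mortality tables
#'
#' Year \code{i} of the path (ages \code{start_age + i - 1}) takes its
#' fracture hazard from the incidence table (converted from per 100,000
#' person-years to per person-year) and its death hazard from the mortality
#' table. Both tables must cover the starting age; past their last band the
#' hazards are held constant.
#'
#' @param incidence a \code{rate_table} of fracture incidence.
#' @param mortality a \code{rate_table} of annual death hazards
#'   (\code{unit = "per_person_year"}).
#' @param sex "male" or "female".
#' @param start_age starting age in years.
#' @param horizon horizon in years (default 10).
#' @return A \code{hazard_path}.
#' @export
hazard_path_from_tables <- function(incidence, mortality, sex, start_age,
                                    horizon = 10) {
  ages <- start_age + seq_len(horizon) - 1
  f <- vapply(ages, function(a) rate_at(incidence, sex, a), numeric(1))
  if (identical(attr(incidence, "unit"), "per_100k")) f <- f / 1e5
  d <- vapply(ages, function(a) rate_at(mortality, sex, a), numeric(1))
  if (identical(attr(mortality, "unit"), "per_100k")) d <- d / 1e5
  hazard_path(f, d)
}

#' Monte-Carlo oracle for the first-fracture probability
#'
#' Simulates subjects year by year: within each year an exponential fracture
#' time (rate \eqn{f_i}) races an independent exponential death time (rate
#' \eqn{d_i}); a fracture is recorded when the fracture time is both smaller
#' than the death time and under one year. This is an independent check of
#' [ten_year_probability()], not a substitute for it.
#'
#' @param path a \code{hazard_path}.
#' @param n_draws number of simulated subjects (>= 1).
#' @param seed RNG seed (results are reproducible given the seed).
#' @return Fraction of subjects fracturing within the horizon.
#' @export
monte_carlo_probability <- function(path, n_draws, seed) {
  stopifnot(inherits(path, "hazard_path"))
  if (n_draws < 1) value_error("n_draws must be >= 1")
  set.seed(seed)
  n_alive <- as.integer(n_draws)
  fractures <- 0L
  for (i in seq_len(path$horizon)) {
    if (n_alive == 0L) break
    f <- path$fracture[i]
    d <- path$death[i]
    tf <- if (f > 0) stats::rexp(n_alive, f) else rep(Inf, n_alive)
    td <- if (d > 0) stats::rexp(n_alive, d) else rep(Inf, n_alive)
    fractured <- tf < td & tf < 1
    died <- td <= tf & td < 1
    fractures <- fractures + sum(fractured)
    n_alive <- n_alive - sum(fractured) - sum(died)
  }
  fractures / n_draws
}

#' @export
print.hazard_path <- function(x, ...) {
  cat(sprintf("hazard_path: horizon %d year(s)\n", x$horizon))
  print(data.frame(year = seq_len(x$horizon),
                   fracture = x$fracture, death = x$death), ...)
  invisible(x)
}
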