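# The four analysis stages: MOF imputation, surrogate-model assembly,
# grid-wise model comparison, and national burden projection.

#' Impute MOF incidence from hip incidence via ratio tables
#'
#' When a country records hip fractures only, the incidence of the other major
#' osteoporotic fracture (MOF) sites is imputed on the assumption that the
#' age- and sex-specific MOF:hip ratio matches a reference pattern (high
#' ratios around age 50 falling towards ~2 in old age, the shape seen
#' wherever full MOF registration exists). Each hip band's rate is multiplied
#' by the ratio applying at the band's start age.
#'
#' @param hip a \code{rate_table} of hip fracture incidence (per 100k).
#' @param ratios a \code{ratio_table} covering every hip band.
#' @return A \code{rate_table} of imputed MOF incidence, labelled with its
#'   provenance.
#' @export
impute_mof_incidence <- function(hip, ratios) {
  for (s in unique(hip$sex)) {
    hb <- hip[hip$sex == s, , drop = FALSE]
    rb <- ratios[ratios$sex == s, , drop = FALSE]
    if (nrow(rb) == 0) coverage_error(sprintf("ratio table has no bands for sex %s", s))
    if (rb$age_start[1] > hb$age_start[1]) {
      coverage_error(sprintf(
        "ratio table does not cover hip bands below age %g for sex %s",
        rb$age_start[1], s))
    }
    last_end <- max(rb$age_end)
    uncovered <- hb$age_start[hb$age_start >= last_end]
    if (length(uncovered)) {
      coverage_error(sprintf(
        "ratio table ends at age %g and does not cover hip band(s) [%g,%s) for sex %s",
        last_end, uncovered[1],
        format(hb$age_end[match(uncovered[1], hb$age_start)]), s))
    }
  }
  out <- as.data.frame(hip)
  out$rate <- vapply(seq_len(nrow(out)), function(i) {
    out$rate[i] * rate_at(ratios, out$sex[i], out$age_start[i])
  }, numeric(1))
  rate_table(out, unit = attr(hip, "unit"),
             label = sprintf("MOF imputed from '%s' via '%s'",
                             attr(hip, "label"), attr(ratios, "label")))
}

#' Assemble a surrogate fracture-probability model
#'
#' A surrogate model combines a donor country's age- and sex-specific hip
#' fracture incidence (with MOF incidence imputed from it) with the index
#' country's own mortality. Supplying the donor's own mortality instead
#' yields the donor's authentic model, so the same constructor builds both
#' sides of a comparison.
#'
#' @param hip_incidence donor-country hip incidence (\code{rate_table},
#'   per 100k) covering at least ages 50-90 for both sexes.
#' @param mortality index-country annual death hazards (\code{rate_table},
#'   per person-year), same coverage.
#' @param ratios MOF:hip \code{ratio_table} covering the hip bands.
#' @param risk_model a \code{risk_factor_model}.
#' @param label model label (e.g. index country name).
#' @return A \code{frax_model} with slots \code{hip_incidence},
#'   \code{mof_incidence}, \code{mortality}, \code{risk_model}, \code{label}.
#' @export
assemble_surrogate <- function(hip_incidence, mortality, ratios,
                               risk_model = risk_factor_model(),
                               label = "surrogate model") {
  assert_covers(hip_incidence, 50, 90, what = "hip incidence")
  assert_covers(mortality, 50, 90, what = "mortality")
  mof <- impute_mof_incidence(hip_incidence, ratios)
  stopifnot(all(mof$rate >= hip_incidence$rate))
  structure(list(hip_incidence = hip_incidence, mof_incidence = mof,
                 mortality = mortality, risk_model = risk_model,
                 label = label,
                 metadata = list(incidence_source = attr(hip_incidence, "label"),
                                 mortality_source = attr(mortality, "label"),
                                 ratio_source = attr(ratios, "label"))),
            class = "frax_model")
}

#' 10-year fracture probabilities for one profile under one model
#'
#' Builds the subject's yearly hazard paths from the model's incidence and
#' mortality tables, applies the risk-factor multiplier to the fracture
#' hazards, and returns the competing-risk first-fracture probabilities for
#' both outcomes.
#'
#' @param model a \code{frax_model}.
#' @param profile a \code{risk_profile} (age >= 50).
#' @param horizon horizon in years (default 10).
#' @return A \code{probability_estimate}: list with \code{p_hip},
#'   \code{p_mof}, \code{age}, \code{sex} and the profile.
#' @export
model_probability <- function(model, profile, horizon = 10) {
  if (profile$age < 50) domain_error("the model is undefined below age 50")
  p <- vapply(c("hip", "mof"), function(outcome) {
    inc <- if (outcome == "hip") model$hip_incidence else model$mof_incidence
    base <- hazard_path_from_tables(inc, model$mortality, profile$sex,
                                    profile$age, horizon)
    ten_year_probability(adjusted_hazard_path(base, profile, model$risk_model,
                                              outcome))
  }, numeric(1))
  structure(list(p_hip = p[["hip"]], p_mof = p[["mof"]],
                 age = profile$age, sex = profile$sex, profile = profile),
            class = "probability_estimate")
}

#' Compare two models over a profile grid
#'
#' Computes the paired 10-year probabilities of both models for every profile
#' in the grid and summarises their agreement: Pearson correlation, ordinary
#' least-squares slope and intercept of model B on model A, and Spearman rank
#' correlation (the rank-order concordance that determines whether the two
#' models sort subjects identically by risk).
#'
#' @param model_a,model_b \code{frax_model} objects covering the grid's ages.
#' @param grid a \code{profile_grid}.
#' @param outcome "hip" or "mof".
#' @param horizon horizon in years (default 10).
#' @return A \code{model_comparison}: paired probabilities (in grid order)
#'   plus \code{pearson_r}, \code{spearman_rho}, \code{slope},
#'   \code{intercept}, \code{outcome}, \code{ages}, \code{sex} and labels.
#' @export
compare_models <- function(model_a, model_b, grid, outcome = c("hip", "mof"),
                           horizon = 10) {
  outcome <- match.arg(outcome)
  p_a <- grid_probabilities(model_a, grid, outcome, horizon)
  p_b <- grid_probabilities(model_b, grid, outcome, horizon)
  if (length(p_a) < 2 || stats::sd(p_a) == 0 || stats::sd(p_b) == 0) {
    comparison_error("probabilities have zero variance under at least one model; r is undefined")
  }
  fit <- stats::lm(p_b ~ p_a)
  structure(list(
    pairs = data.frame(key = vapply(grid$profiles, profile_key, character(1)),
                       p_a = p_a, p_b = p_b),
    pearson_r = stats::cor(p_a, p_b),
    spearman_rho = stats::cor(p_a, p_b, method = "spearman"),
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    outcome = outcome, ages = grid$ages, sex = grid$sex,
    label_a = model_a$label, label_b = model_b$label),
    class = "model_comparison")
}

# Grid-wise probabilities with the base hazard path cached per (age, sex):
# within a stratum every profile shares the same baseline path and differs
# only by its scalar multiplier. Equivalent to model_probability profile by
# profile (asserted in the tests), just without rebuilding the path 512 times.
grid_probabilities <- function(model, grid, outcome, horizon = 10) {
  inc <- if (outcome == "hip") model$hip_incidence else model$mof_incidence
  cache <- new.env(parent = emptyenv())
  vapply(grid$profiles, function(pr) {
    key <- paste(pr$age, pr$sex)
    if (is.null(cache[[key]])) {
      cache[[key]] <- hazard_path_from_tables(inc, model$mortality, pr$sex,
                                              pr$age, horizon)
    }
    base <- cache[[key]]
    m <- hazard_multiplier(pr, model$risk_model, outcome)
    ten_year_probability(hazard_path(base$fracture * m, base$death))
  }, numeric(1))
}

#' Project national fracture counts against population pyramids
#'
#' Applies fixed age- and sex-specific incidence to each year's population
#' pyramid: the expected count in a band is
#' \code{count * rate / 100000}, restricted to bands starting at age 50 or
#' above (the model's domain), using the incidence applying at the band
#' midpoint. Incidence is held at its baseline values for all projection
#' years. Counts are expected values (no sampling); rounding happens only at
#' report time.
#'
#' @param incidence hip (or any) fracture incidence \code{rate_table},
#'   per 100k, covering every pyramid band at ages >= 50.
#' @param pyramids list of \code{population_pyramid} (e.g. from
#'   [read_population()] or [growing_pyramids()]).
#' @param baseline_year year used as the 100% reference of the
#'   percent-of-baseline row; must be among the pyramid years.
#' @return A \code{burden_projection}: per-(year, sex) expected counts,
#'   per-year totals, and \code{percent_of_baseline} =
#'   \code{round(100 * total / total_baseline)} (NA for the baseline year).
#' @export
project_burden <- function(incidence, pyramids, baseline_year) {
  years <- vapply(pyramids, function(p) attr(p, "year"), integer(1))
  if (!baseline_year %in% years) {
    config_error(sprintf("baseline year %d not among the pyramid years (%s)",
                         baseline_year, paste(years, collapse = ", ")))
  }
  by_sex <- do.call(rbind, lapply(pyramids, function(p) {
    rows <- p[p$age_start >= 50, , drop = FALSE]
    counts <- vapply(c("male", "female"), function(s) {
      b <- rows[rows$sex == s, , drop = FALSE]
      if (nrow(b) == 0) return(0)
      mids <- ifelse(is.finite(b$age_end), (b$age_start + b$age_end) / 2,
                     b$age_start + 2.5)
      rates <- vapply(seq_len(nrow(b)), function(i) {
        tryCatch(rate_at(incidence, s, mids[i]),
                 surrofrax_domain_error = function(e) coverage_error(sprintf(
                   "incidence does not cover pyramid band [%g,%g) for sex %s",
                   b$age_start[i], b$age_end[i], s)))
      }, numeric(1))
      sum(b$count * rates / 1e5)
    }, numeric(1))
    data.frame(year = attr(p, "year"), sex = c("male", "female"),
               count = unname(counts))
  }))
  burden_projection(by_sex, baseline_year)
}

#' @rdname project_burden
#' @param by_sex data.frame with columns \code{year}, \code{sex},
#'   \code{count} (expected fracture counts, >= 0).
#' @export
burden_projection <- function(by_sex, baseline_year) {
  if (any(by_sex$count < 0)) value_error("fracture counts must be >= 0")
  totals <- stats::aggregate(count ~ year, by_sex, sum)
  names(totals)[2] <- "total"
  totals <- totals[order(totals$year), ]
  if (!baseline_year %in% totals$year) {
    config_error(sprintf("baseline year %d absent from the projection", baseline_year))
  }
  base_total <- totals$total[totals$year == baseline_year]
  totals$percent_of_baseline <- ifelse(
    totals$year == baseline_year, NA_real_,
    round(100 * totals$total / base_total))
  structure(list(by_sex = by_sex[order(by_sex$year, by_sex$sex), ],
                 totals = totals, baseline_year = baseline_year),
            class = "burden_projection")
}

#' Format a burden projection as a publication-style table
#'
#' Rows Men / Women / Total / Increase (%) by projection year, counts rounded
#' to whole fractures. The Increase row is 100 times the ratio of each year's
#' total to the baseline total, rounded to an integer (so a year matching the
#' baseline reads 100); the baseline year's own entry is NA, conventionally
#' printed as "-".
#'
#' @param projection a \code{burden_projection}.
#' @return A data.frame with one column per year and row names
#'   \code{Men, Women, Total, Increase (%)}.
#' @export
summarise_table1 <- function(projection) {
  stopifnot(inherits(projection, "burden_projection"))
  years <- projection$totals$year
  get_sex <- function(s) vapply(years, function(y) {
    sum(projection$by_sex$count[projection$by_sex$year == y &
                                  projection$by_sex$sex == s])
  }, numeric(1))
  men <- round(get_sex("male"))
  women <- round(get_sex("female"))
  out <- rbind(Men = men, Women = women, Total = round(projection$totals$total),
               `Increase (%)` = projection$totals$percent_of_baseline)
  colnames(out) <- years
  as.data.frame(out)
}

#' @export
print.frax_model <- function(x, ...) {
  cat(sprintf("frax_model: %s\n", x$label))
  cat(sprintf("  hip incidence : %s\n", x$metadata$incidence_source))
  cat(sprintf("  MOF incidence : %s\n", attr(x$mof_incidence, "label")))
  cat(sprintf("  mortality     : %s\n", x$metadata$mortality_source))
  cat(sprintf("  risk model    : %s\n", x$risk_model$label))
  invisible(x)
}

#' @export
print.probability_estimate <- function(x, ...) {
  cat(sprintf("10-year probabilities at age %g (%s): hip %.4f, MOF %.4f\n",
              x$age, x$sex, x$p_hip, x$p_mof))
  invisible(x)
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("model_comparison (%s, %s, age(s) %s): '%s' vs '%s'\n",
              toupper(x$outcome), x$sex, paste(x$ages, collapse = "/"),
              x$label_a, x$label_b))
  cat(sprintf("  n = %d pairs; Pearson r = %.4f; Spearman rho = %.4f\n",
              nrow(x$pairs), x$pearson_r, x$spearman_rho))
  cat(sprintf("  OLS of B on A: slope = %.4f, intercept = %.5f\n",
              x$slope, x$intercept))
  invisible(x)
}

#' Scatter plot of paired model probabilities with the identity line
#'
#' @param x a \code{model_comparison}.
#' @param ... passed to [plot()].
#' @export
plot.model_comparison <- function(x, ...) {
  plot(x$pairs$p_a, x$pairs$p_b,
       xlab = sprintf("%s probability, %s", toupper(x$outcome), x$label_a),
       ylab = sprintf("%s probability, %s", toupper(x$outcome), x$label_b),
       main = sprintf("r = %.4f", x$pearson_r), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' @export
print.burden_projection <- function(x, ...) {
  cat(sprintf("burden_projection: %d year(s), baseline %d\n",
              nrow(x$totals), x$baseline_year))
  print(summarise_table1(x))
  invisible(x)
}
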