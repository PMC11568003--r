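test_that("MOF imputation multiplies hip rates band-wise", {
  hip <- gompertz_rate_table(gompertz_params(25, 0.11, 2),
                             label = "hip fixture")
  # identity ratios leave the table unchanged
  same <- impute_mof_incidence(hip, flat_ratios(1))
  expect_equal(same$rate, hip$rate)

  # constant ratio 3: every band triples
  tripled <- impute_mof_incidence(hip, flat_ratios(3))
  expect_equal(tripled$rate, hip$rate * 3)

  # 40 per 100k with ratio 3 -> 120 per 100k
  one_band <- rate_table(data.frame(sex = "male", age_start = 50,
                                    age_end = Inf, rate = 40), "per_100k")
  expect_equal(impute_mof_incidence(one_band, flat_ratios(3))$rate, 120)

  # age-varying ratios pick the band at each hip band's start
  varying <- default_mof_ratios()
  mof <- impute_mof_incidence(hip, varying)
  i <- which(hip$sex == "female" & hip$age_start == 70)
  expect_equal(mof$rate[i], hip$rate[i] * rate_at(varying, "female", 70))
})

test_that("MOF imputation demands full ratio coverage", {
  hip <- rate_table(data.frame(sex = rep("male", 4),
                               age_start = c(50, 60, 70, 80),
                               age_end = c(60, 70, 80, 90),
                               rate = c(10, 20, 40, 80)), "per_100k")
  partial <- ratio_table(data.frame(sex = "male", age_start = c(50, 65),
                                    age_end = c(65, 80), ratio = c(4, 3)))
  err <- expect_error(impute_mof_incidence(hip, partial),
                      class = "surrofrax_coverage_error")
  expect_match(conditionMessage(err), "80")
})

test_that("a surrogate with the donor's own mortality is the donor model", {
  pair <- make_country_pair(
    index_mortality_params = gompertz_params(0.003, 0.095, 0.55),
    donor_mortality_params = gompertz_params(0.003, 0.095, 0.55))
  for (age in c(50, 65, 80)) {
    prof <- risk_profile(age, "female", t_score = -1)
    a <- model_probability(pair$donor, prof)
    b <- model_probability(pair$surrogate, prof)
    expect_equal(b$p_hip, a$p_hip, tolerance = 1e-15)
    expect_equal(b$p_mof, a$p_mof, tolerance = 1e-15)
  }
})

test_that("higher index mortality lowers probabilities at old ages", {
  pair <- canonical_pair()
  for (sex in c("male", "female")) {
    for (age in 70:85) {
      prof <- risk_profile(age, sex)
      expect_lte(model_probability(pair$surrogate, prof)$p_hip,
                 model_probability(pair$donor, prof)$p_hip)
      expect_lte(model_probability(pair$surrogate, prof)$p_mof,
                 model_probability(pair$donor, prof)$p_mof)
    }
  }
})

test_that("a donor with ~22% lower incidence yields near-proportionally lower probabilities", {
  pair <- canonical_pair()
  low <- assemble_surrogate(
    gompertz_rate_table(gompertz_params(15 * 0.78, 0.11, 2),
                        label = "second donor"),
    pair$surrogate$mortality, pair$ratios, label = "second-donor surrogate")
  for (age in c(60, 70, 80)) {
    prof <- risk_profile(age, "female")
    ratio <- model_probability(low, prof)$p_hip /
      model_probability(pair$surrogate, prof)$p_hip
    expect_lt(ratio, 1)
    expect_gt(ratio, 0.7)   # near-proportional at small probabilities
    expect_lt(ratio, 0.85)
  }
})

test_that("model probabilities respect domain and dominance invariants", {
  pair <- canonical_pair()
  expect_error(model_probability(pair$donor, risk_profile(49, "male")),
               class = "surrofrax_domain_error")

  zero <- assemble_surrogate(flat_table(0, label = "no fractures"),
                             pair$donor$mortality, pair$ratios)
  expect_equal(model_probability(zero, risk_profile(70, "female"))$p_hip, 0)

  # p_mof >= p_hip whenever ratios >= 1, across random profiles
  set.seed(17)
  for (i in 1:50) {
    prof <- risk_profile(
      age = sample(50:85, 1), sex = sample(c("male", "female"), 1),
      prior_fracture = runif(1) < 0.5, current_smoking = runif(1) < 0.5,
      glucocorticoids = runif(1) < 0.5, rheumatoid_arthritis = runif(1) < 0.5,
      alcohol_high = runif(1) < 0.5, parent_hip_fracture = runif(1) < 0.5,
      t_score = runif(1, -3.5, 0))
    est <- model_probability(pair$surrogate, prof)
    expect_gte(est$p_mof, est$p_hip)
    expect_lte(est$p_mof, 1)
  }

  # doubling all mortality lowers or preserves p at every age
  doubled <- pair$donor
  dm <- as.data.frame(pair$donor$mortality)
  dm$rate <- dm$rate * 2
  doubled$mortality <- rate_table(dm, unit = "per_person_year")
  for (age in seq(50, 85, by = 5)) {
    prof <- risk_profile(age, "male", t_score = -2)
    expect_lte(model_probability(doubled, prof)$p_hip,
               model_probability(pair$donor, prof)$p_hip)
  }
})

test_that("self-comparison yields perfect agreement", {
  pair <- canonical_pair()
  grid <- enumerate_grid(70, t_scores = c(0, -1.5, -3),
                         factor_names = c("prior_fracture", "glucocorticoids"))
  cmp <- compare_models(pair$donor, pair$donor, grid, "hip")
  expect_equal(cmp$pearson_r, 1)
  expect_equal(cmp$spearman_rho, 1)
  expect_equal(cmp$slope, 1, tolerance = 1e-10)
  expect_equal(cmp$intercept, 0, tolerance = 1e-12)
  expect_equal(nrow(cmp$pairs), length(grid$profiles))
})

test_that("comparison summaries match an independent per-profile recomputation", {
  pair <- canonical_pair()
  grid <- enumerate_grid(70, t_scores = c(0, -2),
                         factor_names = c("prior_fracture", "current_smoking"),
                         sex = "male")
  cmp <- compare_models(pair$donor, pair$surrogate, grid, "mof")
  # independent route: model_probability profile by profile, then stats::cor/lm
  p_a <- vapply(grid$profiles, function(pr)
    model_probability(pair$donor, pr)$p_mof, numeric(1))
  p_b <- vapply(grid$profiles, function(pr)
    model_probability(pair$surrogate, pr)$p_mof, numeric(1))
  expect_equal(cmp$pairs$p_a, p_a, tolerance = 1e-14)
  expect_equal(cmp$pairs$p_b, p_b, tolerance = 1e-14)
  expect_equal(cmp$pearson_r, stats::cor(p_a, p_b), tolerance = 1e-12)
  expect_equal(cmp$spearman_rho, stats::cor(p_a, p_b, method = "spearman"),
               tolerance = 1e-12)
  fit <- stats::lm(p_b ~ p_a)
  expect_equal(cmp$slope, unname(coef(fit)[2]), tolerance = 1e-12)
  expect_equal(cmp$intercept, unname(coef(fit)[1]), tolerance = 1e-12)
})

test_that("zero-variance grids make the correlation undefined", {
  pair <- canonical_pair()
  zero <- assemble_surrogate(flat_table(0, label = "no fractures"),
                             pair$donor$mortality, pair$ratios)
  grid <- enumerate_grid(70, t_scores = c(0, -1),
                         factor_names = "prior_fracture")
  expect_error(compare_models(zero, pair$surrogate, grid, "hip"),
               class = "surrofrax_comparison_error")
  single <- enumerate_grid(70, t_scores = 0, factor_names = character(0))
  expect_error(compare_models(pair$donor, pair$surrogate, single, "hip"),
               class = "surrofrax_comparison_error")
})

test_that("burden projection is a band-wise expectation, linear in inputs", {
  inc <- flat_table(100)
  pyr <- population_pyramid(2015, data.frame(sex = "male", age_start = 50,
                                             age_end = 55, count = 10000))
  proj <- project_burden(inc, list(pyr), 2015)
  expect_equal(proj$totals$total, 10)   # 10000 * 100 / 100000

  # linear in population
  pyr2 <- population_pyramid(2015, data.frame(sex = "male", age_start = 50,
                                              age_end = 55, count = 20000))
  expect_equal(project_burden(inc, list(pyr2), 2015)$totals$total, 20)

  # linear in rates
  expect_equal(project_burden(flat_table(200), list(pyr), 2015)$totals$total, 20)

  # bands below 50 are outside the model's domain and excluded
  pyr3 <- population_pyramid(2015, data.frame(sex = "male",
                                              age_start = c(40, 50),
                                              age_end = c(50, 55),
                                              count = c(5000, 10000)))
  expect_equal(project_burden(inc, list(pyr3), 2015)$totals$total, 10)

  # a 50+ band the incidence cannot price is a coverage error
  late_inc <- rate_table(data.frame(sex = "male", age_start = 55,
                                    age_end = Inf, rate = 100), "per_100k")
  expect_error(project_burden(late_inc, list(pyr), 2015),
               class = "surrofrax_coverage_error")

  expect_error(project_burden(inc, list(pyr), 1999),
               class = "surrofrax_config_error")
})

test_that("burden tables are internally consistent", {
  pair <- canonical_pair()
  spec <- canonical_pyramid_spec()
  pyramids <- growing_pyramids(spec$base_counts, spec$growth_per_decade,
                               c(2015, 2030, 2050))
  proj <- project_burden(pair$donor$hip_incidence, pyramids, 2015)
  tab <- summarise_table1(proj)

  # Total row equals Men + Women, every year (row-wise rounding may shift 1)
  expect_true(all(abs(unlist(tab["Total", ]) -
                        (unlist(tab["Men", ]) + unlist(tab["Women", ]))) <= 1))
  expect_equal(proj$totals$total,
               stats::aggregate(count ~ year, proj$by_sex, sum)$count)

  # Increase row is round(100 * total / baseline total), NA at baseline
  expect_true(is.na(tab["Increase (%)", "2015"]))
  expect_equal(unlist(tab["Increase (%)", c("2030", "2050")]),
               round(100 * proj$totals$total[2:3] / proj$totals$total[1]),
               ignore_attr = TRUE)

  # monotone growth scenario -> rising totals
  expect_true(all(diff(proj$totals$total) > 0))
})
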