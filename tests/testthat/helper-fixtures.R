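# Shared fixture builders. All fixtures are constructed in code; nothing is
# read from disk except files the tests themselves write to tempdir().

write_csv_text <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}

# Flat (age-constant) rate table covering 50+ for both sexes.
flat_table <- function(rate, unit = "per_100k", label = "flat") {
  rate_table(data.frame(sex = rep(c("male", "female"), each = 1),
                        age_start = 50, age_end = Inf, rate = rate),
             unit = unit, label = label)
}

# Ratio table with a single constant ratio covering 50+.
flat_ratios <- function(ratio = 1) {
  ratio_table(data.frame(sex = c("male", "female"), age_start = 50,
                         age_end = Inf, ratio = ratio), label = "flat ratios")
}

# Random hazard path with plausible magnitudes (fracture up to ~2%/yr,
# death up to ~15%/yr), reproducible given the seed.
random_path <- function(seed, horizon = 10) {
  set.seed(seed)
  hazard_path(stats::runif(horizon, 0, 0.02), stats::runif(horizon, 0, 0.15))
}

# Death-before-fracture probability over the horizon, computed directly from
# the same within-year exponential-race argument (independent of the
# package's fracture-side code path).
death_first_probability <- function(path) {
  f <- path$fracture; d <- path$death; h <- f + d
  S <- 1; total <- 0
  for (i in seq_along(f)) {
    if (h[i] > 0) {
      total <- total + S * (d[i] / h[i]) * (1 - exp(-h[i]))
      S <- S * exp(-h[i])
    }
  }
  total
}

canonical_pair <- function() make_country_pair()
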