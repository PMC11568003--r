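test_that("well-formed rate CSVs parse into validated tables", {
  path <- write_csv_text(c("sex,age_start,age_end,rate",
                           "male,50,55,40",
                           "male,55,60,60"))
  tab <- read_rate_table(path, "per_100k")
  expect_s3_class(tab, "rate_table")
  expect_equal(nrow(tab), 2)
  expect_equal(tab$rate, c(40, 60))
  expect_identical(attr(tab, "unit"), "per_100k")

  # open-ended last band via the "inf" sentinel
  path2 <- write_csv_text(c("sex,age_start,age_end,rate",
                            "female,50,55,40",
                            "female,55,inf,60"))
  tab2 <- read_rate_table(path2, "per_100k")
  expect_equal(tab2$age_end, c(55, Inf))
})

test_that("malformed tables raise typed errors naming the problem", {
  gap <- write_csv_text(c("sex,age_start,age_end,rate",
                          "male,50,55,40",
                          "male,57,60,60"))
  err <- expect_error(read_rate_table(gap, "per_100k"),
                      class = "surrofrax_structural_error")
  expect_match(conditionMessage(err), "55")
  expect_match(conditionMessage(err), "57")

  overlap <- write_csv_text(c("sex,age_start,age_end,rate",
                              "male,50,56,40",
                              "male,55,60,60"))
  expect_error(read_rate_table(overlap, "per_100k"),
               class = "surrofrax_structural_error")

  negative <- write_csv_text(c("sex,age_start,age_end,rate",
                               "male,50,55,-5"))
  expect_error(read_rate_table(negative, "per_100k"),
               class = "surrofrax_value_error")

  nocol <- write_csv_text(c("sex,age_start,rate", "male,50,40"))
  expect_error(read_rate_table(nocol, "per_100k"),
               class = "surrofrax_format_error")

  open_mid <- write_csv_text(c("sex,age_start,age_end,rate",
                               "male,50,inf,40",
                               "male,55,60,60"))
  expect_error(read_rate_table(open_mid, "per_100k"),
               class = "surrofrax_structural_error")

  expect_error(read_rate_table(tempfile(), "per_100k"),
               class = "surrofrax_format_error")
})

test_that("mortality tables enforce the annual-hazard sanity cap", {
  expect_error(
    rate_table(data.frame(sex = "male", age_start = 50, age_end = Inf, rate = 2.5),
               unit = "per_person_year"),
    class = "surrofrax_value_error")
  ok <- rate_table(data.frame(sex = "male", age_start = 50, age_end = Inf, rate = 0.4),
                   unit = "per_person_year")
  expect_equal(rate_at(ok, "male", 90), 0.4)
})

test_that("population CSVs split into per-year pyramids with validation", {
  path <- write_csv_text(c("year,sex,age_start,age_end,count",
                           "2015,male,50,55,1000",
                           "2015,female,50,55,1100",
                           "2050,male,50,55,2000",
                           "2050,female,50,55,2100"))
  pyr <- read_population(path)
  expect_named(pyr, c("2015", "2050"))
  expect_equal(sum(pyr[["2050"]]$count), 4100)

  dup <- write_csv_text(c("year,sex,age_start,age_end,count",
                          "2015,male,50,55,1000",
                          "2015,male,50,55,900"))
  expect_error(read_population(dup), class = "surrofrax_structural_error")

  neg <- write_csv_text(c("year,sex,age_start,age_end,count",
                          "2015,male,50,55,-10"))
  expect_error(read_population(neg), class = "surrofrax_value_error")

  empty <- write_csv_text("year,sex,age_start,age_end,count")
  expect_warning(out <- read_population(empty), "no population rows")
  expect_length(out, 0)
})

test_that("rate_at uses half-open bands with constant old-age extrapolation", {
  tab <- rate_table(data.frame(sex = "male", age_start = c(50, 55),
                               age_end = c(55, 60), rate = c(40, 60)),
                    unit = "per_100k")
  expect_equal(rate_at(tab, "male", 54.9), 40)
  expect_equal(rate_at(tab, "male", 55.0), 60)   # boundary belongs to later band
  expect_equal(rate_at(tab, "male", 120), 60)    # held constant past last band
  expect_error(rate_at(tab, "male", 49.9), class = "surrofrax_domain_error")
  expect_error(rate_at(tab, "female", 55), class = "surrofrax_domain_error")
})

test_that("rate_at is piecewise constant within every band", {
  tab <- gompertz_rate_table(gompertz_params(25, 0.11, 2))
  set.seed(7)
  for (i in sample(nrow(tab), 20, replace = TRUE)) {
    hi <- if (is.finite(tab$age_end[i])) tab$age_end[i] else tab$age_start[i] + 30
    a <- runif(1, tab$age_start[i], hi - 1e-9)
    expect_equal(rate_at(tab, tab$sex[i], a), tab$rate[i])
  }
})

test_that("write/read round-trips reproduce all numeric fields exactly", {
  tab <- gompertz_rate_table(gompertz_params(25, 0.11, 2), jitter_sd = 0.1,
                             seed = 99)
  path <- tempfile(fileext = ".csv")
  write_rate_table(tab, path)
  back <- read_rate_table(path, "per_100k")
  expect_identical(back$rate, tab$rate)
  expect_identical(back$age_start, tab$age_start)
  expect_identical(back$age_end, tab$age_end)

  ratios <- default_mof_ratios()
  rpath <- tempfile(fileext = ".csv")
  write_rate_table(ratios, rpath)
  expect_identical(read_ratio_table(rpath)$ratio, ratios$ratio)
})

test_that("ratio tables reject ratios below one", {
  expect_error(
    ratio_table(data.frame(sex = "male", age_start = 50, age_end = Inf,
                           ratio = 0.8)),
    class = "surrofrax_value_error")
})
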