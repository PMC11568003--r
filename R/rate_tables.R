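#' Age- and sex-specific rate tables
#'
#' A \code{rate_table} holds event rates in contiguous, non-overlapping,
#' half-open age bands \code{[age_start, age_end)}, separately per sex.
#' Two units are supported: \code{"per_100k"} (events per 100,000
#' person-years, the usual published scale for fracture incidence) and
#' \code{"per_person_year"} (annual hazards, used for mortality). The final
#' band of a sex may be open-ended (\code{age_end = Inf}); beyond the start of
#' the last band the rate is held constant rather than extrapolated.
#'
#' @param data data.frame with columns \code{sex} ("male"/"female"),
#'   \code{age_start}, \code{age_end} (years; \code{Inf} allowed in the last
#'   band of a sex) and \code{rate}.
#' @param unit \code{"per_100k"} or \code{"per_person_year"}.
#' @param label free-text provenance label.
#' @return A validated \code{rate_table} (a data.frame sorted by sex and
#'   \code{age_start}, with \code{unit} and \code{label} attributes).
#' @examples
#' tab <- rate_table(
#'   data.frame(sex = "female", age_start = c(50, 55), age_end = c(55, 60),
#'              rate = c(40, 60)),
#'   unit = "per_100k", label = "example incidence")
#' rate_at(tab, "female", 57)
#' @export
rate_table <- function(data, unit = c("per_100k", "per_person_year"), label = "") {
  unit <- match.arg(unit)
  data <- check_band_frame(data, value_col = "rate")
  if (any(data$rate < 0)) {
    value_error(sprintf("negative rate (%s) at row %d",
                        format(min(data$rate)), which.min(data$rate)))
  }
  if (unit == "per_person_year" && any(data$rate >= 2)) {
    value_error(sprintf("annual hazard %s exceeds the sanity cap of 2 per person-year",
                        format(max(data$rate))))
  }
  structure(data, unit = unit, label = label,
            class = c("rate_table", "data.frame"))
}

#' MOF:hip incidence ratio tables
#'
#' Ratios of major osteoporotic fracture (MOF: hip, clinical spine, distal
#' forearm, proximal humerus) incidence to hip fracture incidence, by age band
#' and sex. Because hip fracture is one of the four MOF sites, every ratio
#' must be at least 1.
#'
#' @param data data.frame with columns \code{sex}, \code{age_start},
#'   \code{age_end}, \code{ratio}.
#' @param label provenance label.
#' @return A validated \code{ratio_table}.
#' @export
ratio_table <- function(data, label = "") {
  data <- check_band_frame(data, value_col = "ratio")
  if (any(data$ratio < 1)) {
    value_error("MOF:hip ratios must be >= 1 (MOF includes hip fractures)")
  }
  structure(data, label = label, class = c("ratio_table", "data.frame"))
}

#' Population pyramid for one calendar year
#'
#' @param year calendar year.
#' @param data data.frame with columns \code{sex}, \code{age_start},
#'   \code{age_end}, \code{count} (persons, non-negative).
#' @return A validated \code{population_pyramid}.
#' @export
population_pyramid <- function(year, data) {
  data <- check_band_frame(data, value_col = "count")
  if (any(data$count < 0)) value_error("negative population count")
  structure(data, year = as.integer(year),
            class = c("population_pyramid", "data.frame"))
}

# Shared band validation: column presence, types, per-sex ordering,
# contiguity, half-open [start, end) semantics, open-ended last band only.
check_band_frame <- function(data, value_col) {
  needed <- c("sex", "age_start", "age_end", value_col)
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols)) {
    format_error(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  data <- as.data.frame(data)[needed]
  data$sex <- as.character(data$sex)
  bad_sex <- setdiff(unique(data$sex), c("male", "female"))
  if (length(bad_sex)) {
    format_error(sprintf("unknown sex value(s): %s", paste(bad_sex, collapse = ", ")))
  }
  for (col in c("age_start", "age_end", value_col)) {
    if (!is.numeric(data[[col]])) {
      format_error(sprintf("column %s is not numeric", col))
    }
    if (any(is.na(data[[col]]))) value_error(sprintf("NA in column %s", col))
  }
  if (any(data$age_start < 0)) value_error("age_start must be >= 0")
  if (any(!is.finite(data$age_start))) value_error("age_start must be finite")
  if (any(data$age_start >= data$age_end)) {
    i <- which(data$age_start >= data$age_end)[1]
    structural_error(sprintf("band %g-%g is empty or inverted",
                             data$age_start[i], data$age_end[i]))
  }
  data <- data[order(data$sex, data$age_start), , drop = FALSE]
  rownames(data) <- NULL
  for (s in unique(data$sex)) {
    rows <- data[data$sex == s, , drop = FALSE]
    if (nrow(rows) > 1) {
      open <- !is.finite(rows$age_end)
      if (any(open[-nrow(rows)])) {
        structural_error(sprintf("open-ended band before the last band for sex %s", s))
      }
      ends <- rows$age_end[-nrow(rows)]
      starts <- rows$age_start[-1]
      if (any(ends > starts)) {
        i <- which(ends > starts)[1]
        structural_error(sprintf("overlapping bands for sex %s at ages %g-%g and %g-%g",
                                 s, rows$age_start[i], rows$age_end[i],
                                 rows$age_start[i + 1], rows$age_end[i + 1]))
      }
      if (any(ends < starts)) {
        i <- which(ends < starts)[1]
        structural_error(sprintf("gap between ages %g and %g for sex %s",
                                 rows$age_end[i], rows$age_start[i + 1], s))
      }
    }
  }
  data
}

#' Look up the rate applying at an exact age
#'
#' Bands are half-open: an age equal to a band boundary belongs to the later
#' band. Ages at or beyond the start of the last band return the last band's
#' rate (the hazard is held constant in extreme old age). Ages below the first
#' band are outside the model's domain and raise an error.
#'
#' @param table a \code{rate_table}, \code{ratio_table} or other band frame.
#' @param sex "male" or "female".
#' @param age age in years (real).
#' @return The rate (or ratio) of the band containing \code{age}.
#' @export
rate_at <- function(table, sex, age) {
  value_col <- band_value_col(table)
  rows <- table[table$sex == sex, , drop = FALSE]
  if (nrow(rows) == 0) domain_error(sprintf("table has no rows for sex %s", sex))
  if (age < rows$age_start[1]) {
    domain_error(sprintf("age %g is below the table's first band (starts at %g)",
                         age, rows$age_start[1]))
  }
  i <- findInterval(age, rows$age_start)
  rows[[value_col]][i]
}

band_value_col <- function(table) {
  if ("rate" %in% names(table)) "rate"
  else if ("ratio" %in% names(table)) "ratio"
  else if ("count" %in% names(table)) "count"
  else format_error("no value column found")
}

# Coverage assertion used by downstream assembly: the table must contain
# every age in [from, to) for each requested sex (constant extrapolation
# past the last band counts as coverage beyond its start).
assert_covers <- function(table, from, to, sexes = c("male", "female"),
                          what = "table") {
  for (s in sexes) {
    rows <- table[table$sex == s, , drop = FALSE]
    if (nrow(rows) == 0) {
      coverage_error(sprintf("%s has no bands for sex %s", what, s))
    }
    if (rows$age_start[1] > from) {
      coverage_error(sprintf("%s does not cover ages [%g,%g) for sex %s: first band starts at %g",
                             what, from, to, s, rows$age_start[1]))
    }
  }
  invisible(TRUE)
}

#' Read a rate table from CSV
#'
#' Expects a UTF-8 comma-separated file with header columns \code{sex},
#' \code{age_start}, \code{age_end}, \code{rate}. An open-ended last band is
#' encoded as \code{age_end = "inf"}.
#'
#' @param path file path.
#' @param unit \code{"per_100k"} (incidence) or \code{"per_person_year"}
#'   (mortality hazard).
#' @param label provenance label; defaults to the file name.
#' @return A validated \code{rate_table}.
#' @export
read_rate_table <- function(path, unit = c("per_100k", "per_person_year"),
                            label = basename(path)) {
  unit <- match.arg(unit)
  rate_table(read_band_csv(path, "rate"), unit = unit, label = label)
}

#' @rdname read_rate_table
#' @export
read_ratio_table <- function(path, label = basename(path)) {
  ratio_table(read_band_csv(path, "ratio"), label = label)
}

read_band_csv <- function(path, value_col) {
  if (!file.exists(path)) format_error(sprintf("file not found: %s", path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", strip.white = TRUE)
  needed <- c("sex", "age_start", "age_end", value_col)
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols)) {
    format_error(sprintf("%s: missing column(s): %s",
                         path, paste(missing_cols, collapse = ", ")))
  }
  parse_num <- function(x, col) {
    x <- ifelse(tolower(x) %in% c("inf", "+inf", "infinity"), "Inf", x)
    out <- suppressWarnings(as.numeric(x))
    if (any(is.na(out))) {
      format_error(sprintf("%s: non-numeric value '%s' in column %s",
                           path, x[which(is.na(out))[1]], col))
    }
    out
  }
  data.frame(
    sex = raw$sex,
    age_start = parse_num(raw$age_start, "age_start"),
    age_end = parse_num(raw$age_end, "age_end"),
    value = parse_num(raw[[value_col]], value_col)
  ) |> stats::setNames(c("sex", "age_start", "age_end", value_col))
}

#' Write a rate table (or ratio table) to CSV
#'
#' Values are serialised at full double precision (17 significant digits) so
#' that \code{read_rate_table(write_rate_table(x))} round-trips every numeric
#' field exactly. Open-ended bands are written as \code{age_end = "inf"}.
#'
#' @param table a \code{rate_table} or \code{ratio_table}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_rate_table <- function(table, path) {
  value_col <- band_value_col(table)
  fmt <- function(x) {
    out <- vapply(x, function(v) {
      if (!is.finite(v)) "inf" else format(v, digits = 17, scientific = FALSE)
    }, character(1))
    out
  }
  out <- data.frame(sex = table$sex,
                    age_start = fmt(table$age_start),
                    age_end = fmt(table$age_end),
                    value = fmt(table[[value_col]]))
  names(out)[4] <- value_col
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read population pyramids from CSV
#'
#' Expects columns \code{year}, \code{sex}, \code{age_start}, \code{age_end},
#' \code{count}; returns one \code{population_pyramid} per distinct year,
#' named by year. Duplicate (year, sex, band) rows are a structural error;
#' a header-only file returns an empty list with a warning.
#'
#' @param path file path.
#' @return Named list of \code{population_pyramid} objects, keyed by year.
#' @export
read_population <- function(path) {
  if (!file.exists(path)) format_error(sprintf("file not found: %s", path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("year", "sex", "age_start", "age_end", "count")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols)) {
    format_error(sprintf("%s: missing column(s): %s",
                         path, paste(missing_cols, collapse = ", ")))
  }
  if (nrow(raw) == 0) {
    warning(sprintf("%s: no population rows, returning an empty list", path))
    return(structure(list(), names = character(0)))
  }
  key <- paste(raw$year, raw$sex, raw$age_start, raw$age_end)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    structural_error(sprintf("duplicate (year, sex, band) rows: %s", d))
  }
  years <- sort(unique(raw$year))
  out <- lapply(years, function(y) {
    population_pyramid(y, raw[raw$year == y, c("sex", "age_start", "age_end", "count")])
  })
  names(out) <- as.character(years)
  out
}

#' Write population pyramids to CSV
#'
#' @param pyramids list of \code{population_pyramid} objects.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_population <- function(pyramids, path) {
  rows <- do.call(rbind, lapply(pyramids, function(p) {
    data.frame(year = attr(p, "year"), sex = p$sex,
               age_start = p$age_start, age_end = p$age_end, count = p$count)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.rate_table <- function(x, ...) {
  cat(sprintf("rate_table: %s [%s], %d band(s), sexes: %s\n",
              attr(x, "label"), attr(x, "unit"), nrow(x),
              paste(sort(unique(x$sex)), collapse = "/")))
  print.data.frame(x, ...)
  invisible(x)
}

#' @export
print.ratio_table <- function(x, ...) {
  cat(sprintf("ratio_table (MOF:hip): %s, %d band(s)\n",
              attr(x, "label"), nrow(x)))
  print.data.frame(x, ...)
  invisible(x)
}

#' @export
print.population_pyramid <- function(x, ...) {
  cat(sprintf("population_pyramid: year %d, %d band(s), total %s persons\n",
              attr(x, "year"), nrow(x), format(round(sum(x$count)), big.mark = ",")))
  print.data.frame(x, ...)
  invisible(x)
}
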