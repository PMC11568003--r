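# Configuration-driven runs. A run configuration is a YAML file naming the
# input tables, model labels, grid specification, risk coefficients,
# projection years and output directory. The run_* functions are the
# programmatic surface behind the command-line wrapper in
# inst/exec/surrofrax.R; every run writes a manifest (inputs, parameters,
# package version, seed) sufficient to reproduce it, and reruns with the same
# configuration produce identical output files (probabilities are serialised
# at 6 decimal places, counts as integers).

#' Read and validate a run configuration
#'
#' @param path YAML file. Recognised blocks: \code{inputs} (paths
#'   \code{donor_hip_incidence}, \code{index_mortality},
#'   \code{donor_mortality}, \code{mof_ratios}, \code{population}),
#'   \code{labels} (\code{donor}, \code{surrogate}), \code{grid} (\code{ages},
#'   \code{t_score_max}, \code{t_score_min}, \code{t_score_step},
#'   \code{factors}, \code{sexes}, \code{bmi}), \code{risk_coefficients}
#'   (\code{hip}, \code{mof}, \code{gradient_of_risk},
#'   \code{reference_t_score}), \code{projection} (\code{baseline_year}),
#'   \code{output_dir}, \code{seed}.
#' @param overrides named list merged over the file's values (shallow per
#'   block), mirroring command-line flag overrides.
#' @return A validated \code{run_config} list.
#' @export
read_run_config <- function(path, overrides = list()) {
  if (!file.exists(path)) config_error(sprintf("config file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  for (nm in names(overrides)) {
    if (is.list(overrides[[nm]]) && is.list(cfg[[nm]])) {
      cfg[[nm]][names(overrides[[nm]])] <- overrides[[nm]]
    } else {
      cfg[[nm]] <- overrides[[nm]]
    }
  }
  defaults <- list(
    labels = list(donor = "donor model", surrogate = "surrogate model"),
    grid = list(ages = c(50, 60, 70, 80), t_score_max = 0, t_score_min = -3.5,
                t_score_step = 0.5,
                factors = RISK_FACTOR_NAMES, sexes = c("male", "female"),
                bmi = 26),
    projection = list(baseline_year = NULL),
    seed = 1L)
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
    else if (is.list(defaults[[nm]])) {
      miss <- setdiff(names(defaults[[nm]]), names(cfg[[nm]]))
      cfg[[nm]][miss] <- defaults[[nm]][miss]
    }
  }
  if (is.null(cfg$output_dir)) config_error("config must name an output_dir")
  if (length(cfg$grid$ages) == 0) config_error("grid.ages must be non-empty")
  if (cfg$grid$t_score_step <= 0) config_error("grid.t_score_step must be positive")
  for (p in unlist(cfg$inputs)) {
    if (!file.exists(p)) config_error(sprintf("input path does not exist: %s", p))
  }
  structure(cfg, class = c("run_config", "list"))
}

config_risk_model <- function(cfg) {
  rc <- cfg$risk_coefficients
  if (is.null(rc)) return(risk_factor_model())
  risk_factor_model(
    hip = if (is.null(rc$hip)) default_hazard_ratios("hip") else unlist(rc$hip),
    mof = if (is.null(rc$mof)) default_hazard_ratios("mof") else unlist(rc$mof),
    gradient_of_risk = if (is.null(rc$gradient_of_risk)) c(hip = 1.8, mof = 1.6)
                       else unlist(rc$gradient_of_risk),
    reference_t_score = if (is.null(rc$reference_t_score)) 0
                        else rc$reference_t_score,
    label = "configured coefficients")
}

config_t_scores <- function(cfg) {
  seq(cfg$grid$t_score_max, cfg$grid$t_score_min, by = -abs(cfg$grid$t_score_step))
}

write_manifest <- function(dir, stage, cfg, extra = list()) {
  manifest <- c(list(
    stage = stage,
    package_version = as.character(utils::packageVersion("surrofrax")),
    seed = cfg$seed,
    inputs = cfg$inputs,
    labels = cfg$labels,
    grid = cfg$grid,
    projection = cfg$projection), extra)
  jsonlite::write_json(manifest, file.path(dir, paste0(stage, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

run_log <- function(...) message(sprintf("[surrofrax] %s", sprintf(...)))

#' Write the full synthetic fixture set
#'
#' Generates the canonical synthetic inputs (two donor hip-incidence tables,
#' index and donor mortality, MOF:hip ratios, and population pyramids from
#' 2015 to 2050 in 5-year steps) into a directory, in the standard CSV
#' schema. Deterministic for a given seed (the seed only matters when
#' \code{jitter_sd > 0}).
#'
#' @param out_dir output directory (created if absent).
#' @param seed RNG seed for optional band jitter.
#' @param jitter_sd band-level log-normal jitter SD (default 0).
#' @return Named list of written file paths.
#' @export
run_generate <- function(out_dir, seed = 1L, jitter_sd = 0) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pair <- make_country_pair(jitter_sd = jitter_sd, seed = seed)
  hip2 <- gompertz_rate_table(gompertz_params(11.7, 0.11, sex_ratio = 2),
                              unit = "per_100k",
                              label = "synthetic second donor hip incidence",
                              jitter_sd = jitter_sd, seed = seed + 3L)
  spec <- canonical_pyramid_spec()
  pyramids <- growing_pyramids(spec$base_counts, spec$growth_per_decade,
                               seq(2015, 2050, by = 5))
  paths <- list(
    donor_hip_incidence = file.path(out_dir, "donor_hip_incidence.csv"),
    donor2_hip_incidence = file.path(out_dir, "donor2_hip_incidence.csv"),
    index_mortality = file.path(out_dir, "index_mortality.csv"),
    donor_mortality = file.path(out_dir, "donor_mortality.csv"),
    mof_ratios = file.path(out_dir, "mof_ratios.csv"),
    population = file.path(out_dir, "population.csv"))
  write_rate_table(pair$donor$hip_incidence, paths$donor_hip_incidence)
  write_rate_table(hip2, paths$donor2_hip_incidence)
  write_rate_table(pair$surrogate$mortality, paths$index_mortality)
  write_rate_table(pair$donor$mortality, paths$donor_mortality)
  write_rate_table(pair$ratios, paths$mof_ratios)
  write_population(pyramids, paths$population)
  run_log("generate: wrote %d fixture file(s) to %s", length(paths), out_dir)
  paths
}

#' Build the surrogate (and donor) models named by a configuration
#'
#' Reads the configured input tables, assembles the surrogate model (donor
#' incidence + index mortality) and, when donor mortality is supplied, the
#' donor's own model, and serialises each model's hip, MOF and mortality
#' tables with a provenance manifest.
#'
#' @param cfg a \code{run_config}.
#' @return Named list of \code{frax_model} (invisible).
#' @export
run_build <- function(cfg) {
  inp <- cfg$inputs
  for (need in c("donor_hip_incidence", "index_mortality", "mof_ratios")) {
    if (is.null(inp[[need]])) config_error(sprintf("config inputs lack '%s'", need))
  }
  hip <- read_rate_table(inp$donor_hip_incidence, "per_100k")
  ratios <- read_ratio_table(inp$mof_ratios)
  rm_model <- config_risk_model(cfg)
  models <- list(
    surrogate = assemble_surrogate(hip, read_rate_table(inp$index_mortality,
                                                        "per_person_year"),
                                   ratios, rm_model, label = cfg$labels$surrogate))
  if (!is.null(inp$donor_mortality)) {
    models$donor <- assemble_surrogate(hip, read_rate_table(inp$donor_mortality,
                                                            "per_person_year"),
                                       ratios, rm_model, label = cfg$labels$donor)
  }
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(models)) {
    mdir <- file.path(cfg$output_dir, paste0("model_", nm))
    dir.create(mdir, recursive = TRUE, showWarnings = FALSE)
    write_rate_table(models[[nm]]$hip_incidence, file.path(mdir, "hip_incidence.csv"))
    write_rate_table(models[[nm]]$mof_incidence, file.path(mdir, "mof_incidence.csv"))
    write_rate_table(models[[nm]]$mortality, file.path(mdir, "mortality.csv"))
    run_log("build: wrote model '%s' to %s", nm, mdir)
  }
  write_manifest(cfg$output_dir, "build", cfg)
  invisible(models)
}

#' Run the grid comparison between the surrogate and donor models
#'
#' For every configured age, sex and outcome, enumerates the risk-factor /
#' T-score grid, computes paired probabilities under both models, and writes
#' one pairs CSV per stratum plus a single summary JSON of Pearson r,
#' Spearman rho, and the least-squares slope and intercept.
#'
#' @param cfg a \code{run_config} whose inputs include
#'   \code{donor_mortality} (the comparison needs both models).
#' @return List of \code{model_comparison}, named
#'   \code{<outcome>_<sex>_age<age>} (invisible).
#' @export
run_compare <- function(cfg) {
  if (is.null(cfg$inputs$donor_mortality)) {
    config_error("comparison requires inputs.donor_mortality")
  }
  models <- run_build(cfg)
  t_scores <- config_t_scores(cfg)
  comparisons <- list()
  summary_rows <- list()
  for (outcome in c("hip", "mof")) {
    for (sex in cfg$grid$sexes) {
      for (age in cfg$grid$ages) {
        grid <- enumerate_grid(age, t_scores, cfg$grid$factors, sex = sex,
                               bmi = cfg$grid$bmi)
        cmp <- compare_models(models$donor, models$surrogate, grid, outcome)
        key <- sprintf("%s_%s_age%d", outcome, sex, age)
        comparisons[[key]] <- cmp
        pairs <- cmp$pairs
        pairs$p_a <- sprintf("%.6f", pairs$p_a)
        pairs$p_b <- sprintf("%.6f", pairs$p_b)
        utils::write.csv(pairs,
                         file.path(cfg$output_dir, paste0("compare_", key, ".csv")),
                         row.names = FALSE, quote = FALSE)
        summary_rows[[key]] <- list(
          outcome = outcome, sex = sex, age = age, n_pairs = nrow(cmp$pairs),
          pearson_r = round(cmp$pearson_r, 6),
          spearman_rho = round(cmp$spearman_rho, 6),
          slope = round(cmp$slope, 6), intercept = round(cmp$intercept, 6))
        run_log("compare: %s r=%.4f slope=%.3f", key, cmp$pearson_r, cmp$slope)
      }
    }
  }
  jsonlite::write_json(summary_rows,
                       file.path(cfg$output_dir, "compare_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_manifest(cfg$output_dir, "compare", cfg)
  invisible(comparisons)
}

#' Project the national fracture burden named by a configuration
#'
#' Applies the configured donor hip incidence to the configured population
#' pyramids and writes a publication-style burden table
#' (Men / Women / Total / Increase (%), one column per year).
#'
#' @param cfg a \code{run_config} whose inputs include \code{population} and
#'   whose projection block names a \code{baseline_year}.
#' @return The \code{burden_projection} (invisible).
#' @export
run_project <- function(cfg) {
  if (is.null(cfg$inputs$population)) config_error("projection requires inputs.population")
  if (is.null(cfg$projection$baseline_year)) {
    config_error("projection requires projection.baseline_year")
  }
  incidence <- read_rate_table(cfg$inputs$donor_hip_incidence, "per_100k")
  pyramids <- read_population(cfg$inputs$population)
  if (!is.null(cfg$projection$years)) {
    pyramids <- pyramids[as.character(cfg$projection$years)]
    if (any(vapply(pyramids, is.null, logical(1)))) {
      config_error("projection.years includes years absent from the population file")
    }
  }
  projection <- project_burden(incidence, pyramids, cfg$projection$baseline_year)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  tab <- summarise_table1(projection)
  out <- cbind(row = rownames(tab), tab)
  utils::write.csv(out, file.path(cfg$output_dir, "burden_table.csv"),
                   row.names = FALSE, quote = FALSE)
  write_manifest(cfg$output_dir, "project", cfg)
  run_log("project: baseline %d total %.0f; final year total %.0f",
          projection$baseline_year, projection$totals$total[1],
          projection$totals$total[nrow(projection$totals)])
  invisible(projection)
}
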