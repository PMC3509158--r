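# Configuration, file I/O and the end-to-end pipeline: survey/trait/soil/
# infiltration tables in, function profiles, diversity metrics,
# multifunctionality indicators, jointness and model tables out.

#' Pipeline configuration
#'
#' Collects the analysis flags that embody the documented design decisions:
#' the arcsine scaling constant for base cations, the threshold set of the
#' proportion indicator, whether CWM weights are restricted to the >= 1\%
#' species set, which soil layer feeds the soil indicators, and the
#' missing-function policy.
#'
#' @param cations_scale Denominator of the cation arcsine square root.
#' @param thresholds Fractions of maximum for the threshold indicator.
#' @param cwm_filtered Restrict CWM weights to the abundance-filtered set?
#' @param soil_layer \code{"topsoil"} (default) or \code{"subsoil"}.
#' @param na_action \code{"error"} or \code{"adjust"} for missing function
#'   values.
#' @return List of class \code{pipeline_config}.
#' @export
pipeline_config <- function(cations_scale = 100,
                            thresholds = c(0.25, 0.5, 0.75),
                            cwm_filtered = FALSE,
                            soil_layer = "topsoil",
                            na_action = "error") {
  check_numeric(thresholds, "thresholds", min = 1e-12, max = 1)
  structure(list(cations_scale = cations_scale, thresholds = thresholds,
                 cwm_filtered = cwm_filtered, soil_layer = soil_layer,
                 na_action = na_action),
            class = "pipeline_config")
}

dataset_tables <- c("plots", "survey", "traits", "soils", "infiltration")

# Format numeric columns at full precision so CSV round-trips are exact.
format_full_precision <- function(df) {
  for (col in names(df)) {
    if (is.double(df[[col]])) {
      v <- sprintf("%.17g", df[[col]])
      v[is.na(df[[col]])] <- NA
      df[[col]] <- v
    }
  }
  df
}

#' Write a fallow dataset as its four delimited input tables
#'
#' Emits \code{plots.csv}, \code{survey.csv}, \code{traits.csv},
#' \code{soils.csv}, \code{infiltration.csv} (UTF-8, comma separated, '.'
#' decimal, header row; doubles at full precision so a read-back is exact)
#' plus a \code{provenance.yaml} with the generating configuration.
#'
#' @param dataset A \code{fallow_dataset}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tab in dataset_tables) {
    utils::write.csv(format_full_precision(dataset[[tab]]),
                     file.path(dir, paste0(tab, ".csv")),
                     row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  }
  prov <- dataset$provenance
  prov$config$calibration_targets <- as.list(prov$config$calibration_targets)
  yaml::write_yaml(prov, file.path(dir, "provenance.yaml"))
  invisible(dir)
}

#' Validate a survey table against its trait table
#'
#' Checks the survey schema and value ranges (reporting offending row
#' numbers) and that every surveyed species has a trait row.
#'
#' @param survey Survey data frame (see \code{\link{species_biomass}}).
#' @param traits Trait table.
#' @return The survey, invisibly; errors describe all problems found.
#' @export
validate_survey <- function(survey, traits) {
  require_columns(survey, c("plot_id", "species_id", "growth_form",
                            "avg_height_m", "cover_class", "dbh_cm",
                            "biovolume_m3"), "survey table")
  problems <- character(0)
  bad_cc <- which(!(survey$cover_class %in% 1:5))
  if (length(bad_cc) > 0) {
    problems <- c(problems, paste0("cover_class outside 1..5 at row(s) ",
                                   paste(bad_cc, collapse = ", ")))
  }
  bad_form <- which(!(survey$growth_form %in% c("tree", "shrub", "herb")))
  if (length(bad_form) > 0) {
    problems <- c(problems, paste0("unknown growth_form at row(s) ",
                                   paste(bad_form, collapse = ", ")))
  }
  for (col in c("avg_height_m", "biovolume_m3")) {
    if (!is.numeric(survey[[col]])) {
      problems <- c(problems, paste0("non-numeric values in ", col))
    } else {
      bad <- which(is.na(survey[[col]]) | survey[[col]] < 0)
      if (length(bad) > 0) {
        problems <- c(problems, paste0("negative or missing ", col,
                                       " at row(s) ", paste(bad, collapse = ", ")))
      }
    }
  }
  unknown <- setdiff(unique(survey$species_id), traits$species_id)
  if (length(unknown) > 0) {
    problems <- c(problems, paste0("species absent from trait table: ",
                                   paste(unknown, collapse = ", ")))
  }
  if (length(problems) > 0) {
    stop_invalid("survey validation failed:\n  ",
                 paste(problems, collapse = "\n  "))
  }
  invisible(survey)
}

#' Read and validate the pipeline's input tables
#'
#' Reads the five CSVs written by \code{\link{write_dataset}} (or prepared
#' to the same schemas), cross-validates them (schema, value ranges with row
#' numbers, survey species present in the trait table) and returns a
#' \code{fallow_dataset}.
#'
#' @param dir Directory containing the CSVs.
#' @return A \code{fallow_dataset}.
#' @export
read_inputs <- function(dir) {
  paths <- file.path(dir, paste0(dataset_tables, ".csv"))
  missing <- !file.exists(paths)
  if (any(missing)) {
    stop_invalid("missing input file(s): ", paste(paths[missing], collapse = ", "))
  }
  tabs <- lapply(paths, function(p) {
    utils::read.csv(p, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  })
  names(tabs) <- dataset_tables
  tabs$survey$dbh_cm <- ifelse(is.na(tabs$survey$dbh_cm), "",
                               as.character(tabs$survey$dbh_cm))
  validate_survey(tabs$survey, tabs$traits)
  require_columns(tabs$soils, c("plot_id", "subplot", "layer", "soc_pct",
                                "mg", "ca", "k", "sand_pct"), "soil table")
  require_columns(tabs$infiltration, c("plot_id", "subplot", "time_min",
                                       "rate_mm_hr"), "infiltration table")
  require_columns(tabs$plots, c("plot_id", "fallow_type"), "plot table")
  if (anyDuplicated(tabs$plots$plot_id)) stop_invalid("duplicate plot ids")
  prov_path <- file.path(dir, "provenance.yaml")
  prov <- if (file.exists(prov_path)) yaml::read_yaml(prov_path) else NULL
  structure(c(tabs, list(provenance = prov)), class = "fallow_dataset")
}

#' Run the full analysis pipeline on a fallow dataset
#'
#' Composes every stage in order: biomass estimation (wood and forage
#' indicators), soil functions (base cations, Horton steady infiltration),
#' function profiles with their transformations, type references
#' (mean-of-3-highest maxima and means), both multifunctionality indicators
#' at all configured thresholds, pairwise jointness in both modes,
#' diversity/trait metrics, and the per-type linear model suites.
#'
#' @param dataset A \code{fallow_dataset} (from
#'   \code{\link{generate_fallow_survey}} or \code{\link{read_inputs}}).
#' @param config A \code{\link{pipeline_config}}.
#' @return List of class \code{fallow_results} with elements
#'   \code{profiles}, \code{reference}, \code{indicators}, \code{jointness},
#'   \code{metrics}, \code{model_data}, \code{models}, \code{log}.
#' @export
run_pipeline <- function(dataset, config = pipeline_config()) {
  validate_survey(dataset$survey, dataset$traits)
  log <- c(sprintf("cations_scale=%g", config$cations_scale),
           sprintf("thresholds=%s", paste(config$thresholds, collapse = ",")),
           sprintf("cwm_filtered=%s", config$cwm_filtered),
           sprintf("soil_layer=%s", config$soil_layer),
           sprintf("na_action=%s", config$na_action),
           "wood_log=ln(x+1)", "grazing_coding=cover-class midpoint")

  wood <- wood_biomass(dataset$survey, dataset$traits)
  forage <- forage_biomass(dataset$survey, dataset$traits)
  soil <- soil_functions(dataset$soils, dataset$infiltration)
  profiles <- function_profiles(dataset$plots, wood, forage, soil,
                                cations_scale = config$cations_scale)
  reference <- type_reference(profiles)
  indicators <- multifunctionality_indicators(profiles, reference,
                                              thresholds = config$thresholds,
                                              na_action = config$na_action)
  joint <- rbind(jointness(profiles, reference, "half_max", config$na_action),
                 jointness(profiles, reference, "above_mean", config$na_action))
  metrics <- diversity_metrics(dataset$survey, dataset$traits,
                               cwm_filtered = config$cwm_filtered)

  model_data <- merge(indicators, metrics, by = "plot_id", all.x = TRUE)
  model_data <- merge(model_data,
                      soil[, c("plot_id", "soc_pct", "sand_pct")],
                      by = "plot_id")
  model_data$soc <- model_data$soc_pct / 100  # fraction scale for the models
  meta_cols <- intersect(c("plot_id", "grazing_class", "grazing_group"),
                         names(dataset$plots))
  model_data <- merge(model_data, dataset$plots[, meta_cols, drop = FALSE],
                      by = "plot_id")
  model_data$grazing <- ifelse(is.na(model_data$grazing_class), NA_real_,
                               cover_class_midpoint(ifelse(is.na(model_data$grazing_class),
                                                           1L, model_data$grazing_class)))

  models <- list()
  if (!"prop_asin_50" %in% names(model_data)) {
    log <- c(log, "model suite skipped: 0.5 threshold not configured")
  } else {
    for (type in unique(model_data$fallow_type)) {
      sub <- model_data[model_data$fallow_type == type, , drop = FALSE]
      n_pred <- if (type == "grazed") 2 else 1
      if (nrow(sub) >= n_pred + 3) {
        models[[type]] <- run_model_suite(sub, type)
      } else {
        log <- c(log, sprintf("model suite skipped for %s (n=%d too small)",
                              type, nrow(sub)))
      }
    }
  }

  structure(list(profiles = profiles, reference = reference,
                 indicators = indicators, jointness = joint,
                 metrics = metrics, model_data = model_data,
                 models = models, log = log),
            class = "fallow_results")
}

#' @export
print.fallow_results <- function(x, ...) {
  cat("Fallow multifunctionality results\n")
  cat("  plots:", nrow(x$profiles), "(",
      paste(sprintf("%d %s", table(x$profiles$fallow_type),
                    names(table(x$profiles$fallow_type))), collapse = ", "),
      ")\n")
  cat("  indicators:", paste(setdiff(names(x$indicators),
                                     c("plot_id", "fallow_type")),
                             collapse = ", "), "\n")
  cat("  model tables:", paste(names(x$models), collapse = ", "), "\n")
  invisible(x)
}

#' Column dictionary for the emitted result tables
#'
#' @return Data frame (\code{table}, \code{column}, \code{description}).
#' @export
data_dictionary <- function() {
  dd <- rbind(
    c("profiles", "wood", "standing woody biomass of trees/large shrubs, t/ha"),
    c("profiles", "forage", "standing green biomass of quality forage species, t/ha"),
    c("profiles", "cations", "topsoil exchangeable Mg+Ca+K, meq/100 g"),
    c("profiles", "infiltration", "Horton steady infiltration rate, mm/hr"),
    c("profiles", "wood_t", "ln(wood + 1)"),
    c("profiles", "forage_t", "sqrt(forage)"),
    c("profiles", "cations_t", "arcsine sqrt of cations / scale constant"),
    c("profiles", "infiltration_t", "sqrt(infiltration)"),
    c("reference", "max3", "mean of the 3 highest transformed values in the type"),
    c("reference", "mean", "mean transformed value in the type"),
    c("indicators", "prop_above_50", "share of the 4 functions at/above 50% of type maximum"),
    c("indicators", "prop_asin_50", "arcsine sqrt of the above (modelling response)"),
    c("indicators", "mpe", "mean % excess of transformed functions over type means"),
    c("jointness", "count", "plots with both functions at/above the mode threshold"),
    c("metrics", "richness", "species with >= 1% of standing green biomass"),
    c("metrics", "fd", "summed UPGMA branch length in standardized ln-trait space"),
    c("metrics", "cwm_n", "green-biomass-weighted mean ln green tissue N%"),
    c("metrics", "cwm_lignin", "green-biomass-weighted mean ln lignin%"),
    c("metrics", "cwm_polyphenol", "green-biomass-weighted mean ln polyphenol%"),
    c("model_data", "soc", "topsoil soil organic carbon, g/g fraction"),
    c("model_data", "grazing", "grazing-score cover-class midpoint, proportion"),
    c("models", "estimate", "OLS coefficient"),
    c("models", "adj_r2", "model R^2 adjusted for number of parameters")
  )
  data.frame(table = dd[, 1], column = dd[, 2], description = dd[, 3],
             stringsAsFactors = FALSE)
}

#' Write pipeline results as CSV tables with a data dictionary
#'
#' @param results A \code{fallow_results}.
#' @param dir Output directory.
#' @return \code{dir}, invisibly.
#' @export
write_results <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tab in c("profiles", "reference", "indicators", "jointness",
                "metrics", "model_data")) {
    utils::write.csv(results[[tab]], file.path(dir, paste0(tab, ".csv")),
                     row.names = FALSE)
  }
  for (type in names(results$models)) {
    utils::write.csv(results$models[[type]],
                     file.path(dir, paste0("models_", type, ".csv")),
                     row.names = FALSE)
  }
  utils::write.csv(data_dictionary(), file.path(dir, "data_dictionary.csv"),
                   row.names = FALSE)
  writeLines(results$log, file.path(dir, "run_log.txt"))
  invisible(dir)
}
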