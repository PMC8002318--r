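# Canonical CSV / data.frame schema for experiment tables. Values are stored
# in display units (kg/h, RPM, %, mm, s); conversion to SI happens once, at
# the model boundary (model_design).

experiment_columns <- function() {
  c("run_id", "dataset_tag", "fr_kg_h", "rpm", "ls_pct",
    "nk", "kb", "nk_per_block", "sa_deg",
    "screw_radius_mm", "knead_thickness_mm", "lead_mm", "convey_len_mm",
    "fe_disc_mm", "powder_density_kg_m3", "liquid_density_kg_m3",
    "mrt_s", "varnorm")
}

#' Experiment table of granulation runs
#'
#' Validates and classes a data.frame of per-run records: operating point,
#' screw geometry and configuration (in display units: kg/h, RPM, %, mm),
#' densities, and the observed responses `mrt_s` (mean residence time,
#' seconds) and optionally `varnorm` (normalized variance). Missing optional
#' columns (`varnorm`, `dataset_tag`) are added as `NA`/`"default"`.
#' Validation aggregates row-level problems into a single error message
#' listing the offending rows.
#'
#' @param df A data.frame with the columns of the canonical schema (see
#'   [read_experiment_csv()] for the list).
#' @return The validated data.frame with class `experiment_table`.
#' @export
experiment_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!"varnorm" %in% names(df)) df$varnorm <- NA_real_
  if (!"dataset_tag" %in% names(df)) df$dataset_tag <- "default"
  if (!"mrt_s" %in% names(df)) df$mrt_s <- NA_real_
  missing_cols <- setdiff(experiment_columns(), names(df))
  if (length(missing_cols) > 0) {
    stop("experiment table is missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[, experiment_columns()]
  num_cols <- setdiff(experiment_columns(), c("run_id", "dataset_tag"))
  problems <- character(0)
  for (col in num_cols) {
    if (!is.numeric(df[[col]])) {
      suppressWarnings(conv <- as.numeric(df[[col]]))
      bad <- which(is.na(conv) & !is.na(df[[col]]))
      if (length(bad) > 0) {
        problems <- c(problems, sprintf("column %s: non-numeric value in row(s) %s",
                                        col, paste(bad, collapse = ", ")))
      }
      df[[col]] <- conv
    }
  }
  if (anyDuplicated(df$run_id)) {
    problems <- c(problems, "run_id values are not unique")
  }
  bad_mrt <- which(!is.na(df$mrt_s) & df$mrt_s <= 0)
  if (length(bad_mrt) > 0) {
    problems <- c(problems, sprintf("mrt_s must be > 0; offending row(s): %s",
                                    paste(bad_mrt, collapse = ", ")))
  }
  bad_var <- which(!is.na(df$varnorm) & df$varnorm <= 0)
  if (length(bad_var) > 0) {
    problems <- c(problems, sprintf("varnorm must be > 0; offending row(s): %s",
                                    paste(bad_var, collapse = ", ")))
  }
  for (col in c("fr_kg_h", "rpm", "screw_radius_mm", "knead_thickness_mm",
                "lead_mm", "fe_disc_mm", "powder_density_kg_m3",
                "liquid_density_kg_m3")) {
    bad <- which(is.na(df[[col]]) | df[[col]] <= 0)
    if (length(bad) > 0) {
      problems <- c(problems, sprintf("%s must be > 0; offending row(s): %s",
                                      col, paste(bad, collapse = ", ")))
    }
  }
  if (length(problems) > 0) {
    stop("experiment table validation failed:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  rownames(df) <- NULL
  class(df) <- c("experiment_table", "data.frame")
  df
}

#' Read an experiment table from CSV
#'
#' Reads the canonical CSV schema (UTF-8, "." decimal): one row per run with
#' columns `run_id, dataset_tag, fr_kg_h, rpm, ls_pct, nk, kb, nk_per_block,
#' sa_deg, screw_radius_mm, knead_thickness_mm, lead_mm, convey_len_mm,
#' fe_disc_mm, powder_density_kg_m3, liquid_density_kg_m3, mrt_s, varnorm`.
#' `varnorm` and `dataset_tag` are optional. Validation errors list the
#' offending rows.
#'
#' @param path Path to a CSV file.
#' @return An [experiment_table()].
#' @export
read_experiment_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(run_id = "character"))
  experiment_table(df)
}

#' Write an experiment table to CSV
#'
#' Writes the canonical schema with a stable column order and fixed numeric
#' formatting (15 significant digits, "." decimal regardless of locale), so
#' identical tables produce byte-identical files.
#'
#' @param table An [experiment_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_experiment_csv <- function(table, path) {
  df <- as.data.frame(table)[, experiment_columns(), drop = FALSE]
  num_cols <- setdiff(experiment_columns(), c("run_id", "dataset_tag"))
  for (col in num_cols) {
    df[[col]] <- vapply(df[[col]], function(v) {
      if (is.na(v)) "" else sprintf("%.15g", v)
    }, character(1))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Published dataset summaries and fitted parameter sets
#'
#' Returns, verbatim, the literature summary of the three collated
#' twin-screw granulation RTD datasets (source, equipment, material, varied
#' factors, run counts) and the model parameter sets fitted on each dataset
#' and on the pooled Kumar set, for use in consistency checks and the
#' reciprocal b1-vs-LS analysis. Two readings of the datasets' average
#' liquid-to-solid percentages circulate (the run-description text and the
#' parameter-comparison list disagree for the two single-source Kumar
#' datasets); both are returned, and the reciprocal-trend analysis uses
#' `ls_avg_pct` (the parameter-comparison list).
#'
#' @return A list with `datasets` (data.frame), `parameters` (data.frame,
#'   one row per fitted set, b5/b6 `NA` where not fitted), and `ls_text_pct`
#'   (named alternative LS reading).
#' @export
published_fixtures <- function() {
  datasets <- data.frame(
    source = c("kumar2015", "kumar2016", "ismail2019"),
    equipment = c("ConsiGma-25", "ConsiGma-25", "Three-Tec"),
    material = c("alpha-lactose monohydrate", "alpha-lactose monohydrate",
                 "Avicel PH-101"),
    varied = c("FR, RPM, NK, SA", "FR, RPM, LS, NK, SA", "FR, RPM, LS, NK"),
    n_points = c(66L, 51L, 24L),
    stringsAsFactors = FALSE
  )
  parameters <- data.frame(
    fit = c("kumar2015", "kumar2015+2016", "kumar2016", "ismail2019"),
    b1 = c(0.33, 0.46, 0.53, 1.67),
    b2 = c(0.99, 1.24, 0.33, 0.96),
    b3 = c(0.65, 1.09, 0.24, 1.32),
    b4 = c(1.33, 1.15, 1.08, 0.63),
    b5 = c(5.35, 2.29, 1.16, NA),
    b6 = c(1.99, 2.24, 1.33, NA),
    ls_avg_pct = c(7, 9.5, 11.5, 85.83),
    stringsAsFactors = FALSE
  )
  list(datasets = datasets,
       parameters = parameters,
       ls_text_pct = c(kumar2015 = 11.5, kumar2016_min = 6, kumar2016_max = 8))
}
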