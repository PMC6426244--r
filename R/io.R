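# Column schemas for the pipeline's CSV interfaces. Each entry names the
# required columns and their readr types; extra columns are preserved.
table_schemas <- function() {
  list(
    incubations = list(
      cols = c(sample_id = "c", bottle_role = "c", d15n = "d",
               nh4_ambient = "d", no2_initial = "d", spike_15n = "d",
               carrier_no2 = "d", t_incubation = "d"),
      optional = c(date = "D", depth_label = "c", diel = "c")
    ),
    standards = list(
      cols = c(standard_id = "c", d15n_known = "d", d15n_measured = "d"),
      optional = c()
    ),
    headspace = list(
      cols = c(sample_id = "c", date = "D", x_headspace = "d", x_air = "d",
               temp_equil = "d", temp_insitu = "d", pressure = "d",
               under_ice = "l"),
      optional = c(depth_label = "c", v_bottle = "d", v_headspace = "d")
    ),
    chla = list(
      cols = c(sample_id = "c", a665_before = "d", a750_before = "d",
               a665_after = "d", a750_after = "d", v_extract = "d",
               v_filtered = "d", path_length = "d"),
      optional = c(replicate = "i")
    ),
    seasonal = list(
      cols = c(date = "D", season = "c", depth_label = "c", diel = "c",
               nh4 = "d", no3no2 = "d", o2 = "d", temp = "d",
               light_fraction = "d", under_ice = "l"),
      optional = c(chla = "d", ao_rate = "d", ao_rate_true = "d",
                   delta_n2o = "d", delta_n2o_ppm = "d")
    )
  )
}

#' Read a validated pipeline table
#'
#' Reads one of the pipeline's CSV interfaces (UTF-8, ISO-8601 dates, decimal
#' point) and validates it against its schema: required columns must be
#' present and parse cleanly, and an empty file is an error. Problem messages
#' name the offending column.
#'
#' @param path Path to a CSV file.
#' @param schema One of `"incubations"`, `"standards"`, `"headspace"`,
#'   `"chla"`, `"seasonal"`.
#' @return A tibble.
#' @export
read_table <- function(path, schema) {
  schemas <- table_schemas()
  if (!schema %in% names(schemas)) {
    rlang::abort(paste("unknown schema:", schema))
  }
  sc <- schemas[[schema]]
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(out) == 0) rlang::abort(paste0("no records in ", path))
  missing_cols <- setdiff(names(sc$cols), names(out))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0(path, ": missing column(s) ",
                        paste(missing_cols, collapse = ", ")))
  }
  types <- c(sc$cols, sc$optional)
  for (cl in intersect(names(types), names(out))) {
    out[[cl]] <- switch(types[[cl]],
      c = as.character(out[[cl]]),
      d = ensure_numeric(out[[cl]], cl, path),
      i = as.integer(out[[cl]]),
      l = ensure_logical(out[[cl]], cl, path),
      D = ensure_date(out[[cl]], cl, path)
    )
  }
  out
}

ensure_numeric <- function(x, col, path) {
  y <- suppressWarnings(as.numeric(x))
  if (any(is.na(y) & !is.na(x))) {
    rlang::abort(paste0(path, ": column '", col, "' has unparseable numbers (row ",
                        which(is.na(y) & !is.na(x))[1], ")"))
  }
  y
}

ensure_logical <- function(x, col, path) {
  y <- as.logical(x)
  if (any(is.na(y) & !is.na(x))) {
    rlang::abort(paste0(path, ": column '", col, "' is not logical"))
  }
  y
}

ensure_date <- function(x, col, path) {
  y <- tryCatch(as.Date(x), error = function(e) rep(NA, length(x)))
  if (any(is.na(y) & !is.na(x))) {
    rlang::abort(paste0(path, ": column '", col, "' has unparseable dates"))
  }
  y
}

#' Write a pipeline table
#'
#' Plain UTF-8 CSV with ISO-8601 dates; the deterministic complement of
#' [read_table()].
#'
#' @param data A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(data, path) {
  readr::write_csv(data, path)
  invisible(path)
}

#' Run the full measurement pipeline on a fixture bundle
#'
#' Executes every stage end-to-end from a directory of schema-conformant CSVs
#' (such as one written by [make_fixture_suite()]): fits the delta
#' calibration from the standards, estimates AO rates with Monte-Carlo
#' uncertainties, solves the headspace records for dissolved N2O, computes
#' chlorophyll a with replicate summaries, and runs the drivers analysis
#' (forward-selection regression and regression tree of AO rate on NH4+, O2,
#' temperature and light, plus season/depth/diel factors) on the seasonal
#' table.
#'
#' @param dir Directory containing `standards.csv`, `incubations.csv`,
#'   `headspace.csv`, `chla.csv`, `seasonal.csv`.
#' @param mc_draws Monte-Carlo draws per incubation (default 500).
#' @param seed Integer seed used for every stochastic step.
#' @param out_dir Optional directory to write result CSVs and a JSON model
#'   summary into.
#' @return A named list: `calibration`, `rates`, `n2o`, `chla`, `mlr`, `urt`,
#'   `seed`.
#' @export
run_pipeline <- function(dir, mc_draws = 500, seed = 1L, out_dir = NULL) {
  standards <- read_table(file.path(dir, "standards.csv"), "standards")
  incubations <- read_table(file.path(dir, "incubations.csv"), "incubations")
  headspace <- read_table(file.path(dir, "headspace.csv"), "headspace")
  chla_in <- read_table(file.path(dir, "chla.csv"), "chla")
  seasonal <- read_table(file.path(dir, "seasonal.csv"), "seasonal")

  calibration <- calibrate_delta(numeric(0), standards$d15n_measured,
                                 standards$d15n_known)
  rates <- estimate_ao_rates(incubations, calibration, mc_draws = mc_draws,
                             seed = seed)
  n2o <- n2o_results(dplyr::arrange(headspace, .data$date))
  chla_out <- chla_summary(lorenzen_chla(chla_in))
  mlr <- forward_mlr(seasonal, "ao_rate",
                     c("nh4", "o2", "temp", "light_fraction"))
  urt <- fit_urt(seasonal, "ao_rate",
                 c("nh4", "o2", "temp", "light_fraction",
                   "season", "depth_label", "diel"),
                 seed = seed)
  out <- list(calibration = calibration, rates = rates, n2o = n2o,
              chla = chla_out, mlr = mlr, urt = urt, seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_table(rates, file.path(out_dir, "rates.csv"))
    write_table(n2o, file.path(out_dir, "n2o.csv"))
    write_table(chla_out, file.path(out_dir, "chla_summary.csv"))
    jsonlite::write_json(
      list(
        seed = seed,
        calibration = glance(calibration),
        mlr = list(selected = mlr$selected, r_squared = mlr$r2,
                   coefficients = tidy(mlr)),
        urt = list(splits = urt$splits, r_squared = urt$r2,
                   leaf_means = urt$leaf_means)
      ),
      file.path(out_dir, "models.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, dataframe = "rows"
    )
  }
  out
}
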