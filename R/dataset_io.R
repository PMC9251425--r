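dataset_schemas <- function() {
  list(
    baseline = c("participant_id", "male", "age", "rural", "education",
                 "met", "smoking", "alcohol", "cvd_cancer", "baseline_year"),
    recalls = c("participant_id", "year", "day", "group_id", "grams", "kcal"),
    waves = c("participant_id", "wave_year", "weight", "height", "sbp", "dbp",
              "fpg", "hba1c", "self_hypertension", "htn_medication",
              "self_diabetes", "diabetes_medication"),
    truth = c("participant_id", "true_index_z")
  )
}

check_schema <- function(tables) {
  schemas <- dataset_schemas()
  for (nm in names(schemas)) {
    if (is.null(tables[[nm]])) stop("dataset table missing: ", nm)
    absent <- setdiff(schemas[[nm]], names(tables[[nm]]))
    if (length(absent) > 0L) {
      stop(sprintf("table `%s` lacks required column(s): %s",
                   nm, paste(absent, collapse = ", ")))
    }
  }
  invisible(tables)
}

# polynomial hash of the JSON-serialized config; stable across sessions
config_hash <- function(config) {
  json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(json))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

# write.csv loses ulps on unrounded doubles; print at 17 significant digits
write_table_exact <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      x <- sprintf("%.17g", out[[j]])
      x[is.na(out[[j]])] <- NA_character_
      out[[j]] <- x
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA")
}

#' Write a synthetic dataset to CSV with a manifest
#'
#' Writes `baseline.csv`, `recalls.csv`, `waves.csv`, `truth.csv` and a
#' `manifest.json` recording the seed, a config hash and per-table row
#' counts. Numeric columns are printed at full precision so a read-back
#' reproduces the values exactly.
#'
#' @param dataset a `pdi_dataset` from [simulate_cohort()], or any list with
#'   the same tables.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  check_schema(dataset)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(dataset_schemas())) {
    write_table_exact(dataset[[nm]], file.path(dir, paste0(nm, ".csv")))
  }
  manifest <- list(
    seed = dataset$config$seed,
    config_hash = config_hash(dataset$config),
    n_participants = nrow(dataset$baseline),
    rows = lapply(dataset[names(dataset_schemas())], nrow)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir directory containing the CSV tables and `manifest.json`.
#' @return a `pdi_dataset` (without the full config; the manifest is
#'   attached as element `manifest`).
#' @export
read_dataset <- function(dir) {
  tables <- lapply(names(dataset_schemas()), function(nm) {
    path <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(path)) stop("dataset table missing: ", nm)
    utils::read.csv(path, stringsAsFactors = FALSE)
  })
  names(tables) <- names(dataset_schemas())
  check_schema(tables)
  manifest_path <- file.path(dir, "manifest.json")
  tables$manifest <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  }
  structure(tables, class = "pdi_dataset")
}
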