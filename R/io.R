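## CSV plumbing: schema-checked readers/writers for the pipeline's
## interchange tables, the default fragment library, and run manifests.
## All interchange files are RFC 4180 CSV with a header row, UTF-8.

.requireColumns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")))
  invisible(df)
}

#' Read a fragment library
#'
#' Columns: `metabolite`, `fragment_id`, `formula` (elemental formula of the
#' derivatized fragment ion; phosphorus is monoisotopic and omitted),
#' `n_backbone` (tracer-traceable backbone carbons).
#'
#' @param path CSV path; default is the shipped TBDMS M-57 library covering
#'   the measured metabolite panel
#' @return data.frame
#' @export
readFragmentLibrary <- function(path = defaultFragmentLibraryPath()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .requireColumns(df, c("metabolite", "fragment_id", "formula", "n_backbone"),
                  paste("fragment library", path))
  for (i in seq_len(nrow(df))) parseFormula(df$formula[i])  # fail early
  df
}

#' @rdname readFragmentLibrary
#' @export
defaultFragmentLibraryPath <- function() {
  system.file("extdata", "fragment_library.csv", package = "sirmtools",
              mustWork = TRUE)
}

#' Read/write long-format MID tables
#'
#' Columns: `sample_id`, `metabolite`, `fragment_id`, `shift`, `value`,
#' `corrected` (logical: raw intensity vs natural-abundance-corrected
#' fraction).
#'
#' @param path CSV path
#' @return data.frame (for the reader); the writer returns `path` invisibly
#' @export
readMidTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .requireColumns(df, c("sample_id", "metabolite", "fragment_id", "shift",
                        "value", "corrected"), paste("MID table", path))
  df
}

#' @rdname readMidTable
#' @param table data.frame in the MID schema
#' @export
writeMidTable <- function(table, path) {
  .requireColumns(table, c("sample_id", "metabolite", "fragment_id", "shift",
                           "value", "corrected"), "MID table")
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Read an NMR integral table
#'
#' Columns: `sample_id`, `metabolite`, `resonance`, `center`, `satellites`,
#' `tsp`, `protons`.
#'
#' @param path CSV path
#' @return data.frame
#' @export
readNmrTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .requireColumns(df, c("sample_id", "metabolite", "resonance", "center",
                        "satellites", "tsp", "protons"),
                  paste("NMR integral table", path))
  df
}

#' Read a media concentration table
#'
#' Columns: `sample_id`, `line`, `metabolite`, `fresh_mM`, `end_mM`,
#' `volume_ml`, `protein_mg`.
#'
#' @param path CSV path
#' @return data.frame
#' @export
readMediaTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .requireColumns(df, c("sample_id", "line", "metabolite", "fresh_mM",
                        "end_mM", "volume_ml", "protein_mg"),
                  paste("media table", path))
  df
}

#' Read a GC-MS profiling table
#'
#' Columns: `sample_id`, `line`, `metabolite`, `quant_ion_intensity`,
#' `is_intensity`, `protein_mg`.
#'
#' @param path CSV path
#' @return data.frame
#' @export
readProfilingTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .requireColumns(df, c("sample_id", "line", "metabolite",
                        "quant_ion_intensity", "is_intensity", "protein_mg"),
                  paste("profiling table", path))
  df
}

#' Write a run manifest
#'
#' Records command, seed, input/output paths, the isotope abundance table
#' version and the package version alongside a stage's outputs, so that
#' deterministic stages can be reproduced bit-for-bit.
#'
#' @param dir output directory (one manifest per output directory)
#' @param command stage name
#' @param seed integer seed used
#' @param inputs,outputs character vectors of paths
#' @param config named list of parameter values in effect (defaults included)
#' @return the manifest path, invisibly
#' @export
writeRunManifest <- function(dir, command, seed = NA_integer_,
                             inputs = character(0), outputs = character(0),
                             config = list()) {
  manifest <- list(
    command = command,
    seed = seed,
    inputs = inputs,
    outputs = outputs,
    config = config,
    abundance_table = .ABUNDANCE_VERSION,
    package_version = as.character(utils::packageVersion("sirmtools")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a flat key=value config file
#'
#' One `key = value` pair per line; `#` comments and blank lines ignored.
#' Keys carry explicit units where applicable (e.g. `volume_ml`). Values
#' that parse as numbers are returned numeric.
#'
#' @param path config file path
#' @return named list
#' @export
readKeyValueConfig <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      stop("malformed config line (expected key = value): '", ln, "'")
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}
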