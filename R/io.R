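#' Read a replicate-level measurement table
#'
#' Reads and validates the package's plain-text exchange format: a
#' CSV/TSV file (delimiter inferred from the extension, `.csv` = comma,
#' anything else = tab) with required columns `line_id`, `condition`,
#' `component`, `replicate_id`, `value` and optional `marker` and `unit`.
#' Validation errors cite the offending row numbers; duplicate
#' `(line_id, component, replicate_id)` keys, unknown components and
#' non-numeric values are rejected.  Row order never influences
#' downstream results.
#'
#' @param path file path.
#' @param panel panel definition used to validate component names.
#' @return validated data frame.
#' @export
read_measurements <- function(path, panel = marker_panel()) {
  df <- read_table_file(path)
  need <- c("line_id", "condition", "component", "replicate_id", "value")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0L) stop("empty measurement table: ", path, call. = FALSE)
  bad_comp <- !(df$component %in% panel$component)
  if (any(bad_comp)) {
    stop("unknown component(s) at row(s) ",
         paste(utils::head(which(bad_comp), 10), collapse = ", "), ": ",
         paste(unique(df$component[bad_comp]), collapse = ", "),
         call. = FALSE)
  }
  vals <- suppressWarnings(as.numeric(df$value))
  if (any(is.na(vals) & !is.na(df$value))) {
    stop("non-numeric value(s) at row(s) ",
         paste(utils::head(which(is.na(vals) & !is.na(df$value)), 10),
               collapse = ", "), call. = FALSE)
  }
  df$value <- vals
  key <- paste(df$line_id, df$component, df$replicate_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop("duplicate (line_id, component, replicate_id) key: ",
         gsub("\r", " / ", d), " (row ",
         which(key == d)[2], ")", call. = FALSE)
  }
  df
}

#' Read a cell-line metadata table
#'
#' Required columns: `line_id`, `condition`, `donor_age`.  Condition
#' labels must be one of young, midage, old, replicative, artificial,
#' HGPS, WS (or progeria).
#'
#' @param path file path.
#' @return validated data frame.
#' @export
read_meta <- function(path) {
  df <- read_table_file(path)
  need <- c("line_id", "condition", "donor_age")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$line_id)) {
    stop("duplicate line_id in metadata: ",
         df$line_id[duplicated(df$line_id)][1], call. = FALSE)
  }
  ok <- c(panel_conditions(), "HGPS", "WS")
  bad <- setdiff(unique(df$condition), ok)
  if (length(bad) > 0L) {
    stop("unknown condition label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  df$donor_age <- suppressWarnings(as.numeric(df$donor_age))
  df
}

read_table_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a call matrix (indicators as TSV, provenance as JSON)
#'
#' @param calls a [build_call_matrix()] result.
#' @param path output TSV path; per-component adjusted p-values are
#'   written next to it as `<path>.provenance.json` when available.
#' @return invisibly, the TSV path.
#' @export
write_call_matrix <- function(calls, path) {
  write_tsv(as.data.frame(calls), path)
  prov <- attr(calls, "provenance")
  if (!is.null(prov)) {
    jsonlite::write_json(prov, paste0(path, ".provenance.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  invisible(path)
}

#' Run the full panel pipeline on measurement and metadata files
#'
#' Reads replicate-level measurements and metadata, builds the binary
#' call matrix (Dunnett many-to-one against the pooled controls plus the
#' aging-direction gate), scores every line and writes the report bundle
#' plus `calls.tsv` and a
#' machine-readable `run.json` log (effective configuration, input
#' checksums, warnings) into `out_dir`.  Outputs are deterministic
#' functions of the inputs and configuration; rerunning with identical
#' inputs gives byte-identical files.
#'
#' @param measurements_path measurement table path.
#' @param meta_path metadata table path.
#' @param out_dir output directory.
#' @param alpha Dunnett family-wise significance level.
#' @return (invisibly) list with `calls`, `scores`, `frequency`,
#'   `correlation`, `paths`.
#' @export
run_pipeline <- function(measurements_path, meta_path, out_dir,
                         alpha = 0.05) {
  measurements <- read_measurements(measurements_path)
  meta <- read_meta(meta_path)
  warnings_log <- character(0)
  calls <- withCallingHandlers(
    build_call_matrix(measurements, meta, alpha = alpha),
    warning = function(w) {
      warnings_log <<- c(warnings_log, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- score_report(calls, meta, out_dir)
  calls_path <- file.path(out_dir, "calls.tsv")
  write_call_matrix(calls, calls_path)
  log <- list(
    alpha = alpha,
    n_lines = nrow(calls),
    inputs = list(
      measurements = unname(tools::md5sum(measurements_path)),
      meta = unname(tools::md5sum(meta_path))
    ),
    warnings = warnings_log
  )
  jsonlite::write_json(log, file.path(out_dir, "run.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(list(calls = calls), report))
}
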