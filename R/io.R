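# CSV schemas used across the package. Names are the canonical headers.
.assay_schemas <- list(
  trace      = c("time_s", "current_pA"),
  thermogram = c("temp_C", "cp_excess"),
  leakage    = c("time_min", "fluorescence"),
  adsorption = c("conc_uM", "g_ratio", "dphi_mV"),
  ratio      = c("conc_uM", "R"),
  effects    = NULL,                       # compound + free numeric columns
  descriptors = NULL
)

#' Read or write a schema-checked assay table
#'
#' Thin wrappers over CSV IO that validate headers against the package's
#' assay schemas and guard against silent locale corruption: files whose
#' numeric fields use comma decimal marks raise an explicit parse error, and
#' empty files raise an empty-table error. Writing then reading any schema
#' round-trips values exactly (within numeric text representation).
#'
#' @param path File path.
#' @param schema One of `"trace"`, `"thermogram"`, `"leakage"`,
#'   `"adsorption"`, `"ratio"`, `"effects"`, `"descriptors"`.
#' @return `read_assay_table`: a data.frame with the schema's columns.
#' @export
read_assay_table <- function(path, schema = names(.assay_schemas)) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0) stop("empty table: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("empty table (no rows): ", path, call. = FALSE)
  want <- .assay_schemas[[schema]]
  if (!is.null(want)) {
    missing_cols <- setdiff(want, names(df))
    if (length(missing_cols))
      stop(sprintf("schema '%s' mismatch in %s: missing columns %s", schema,
                   path, paste(missing_cols, collapse = ", ")), call. = FALSE)
    check_cols <- want
  } else {
    if (!"compound" %in% names(df))
      stop(sprintf("schema '%s' mismatch in %s: missing column compound",
                   schema, path), call. = FALSE)
    check_cols <- setdiff(names(df), "compound")
  }
  for (cn in check_cols) {
    col <- df[[cn]]
    if (is.character(col)) {
      if (any(grepl("^\\s*-?[0-9]+,[0-9]+\\s*$", col))) {
        stop(sprintf("parse error in %s, column '%s': comma decimal marks are not supported",
                     path, cn), call. = FALSE)
      }
      suppressWarnings(num <- as.numeric(ifelse(col %in% c("na", "NA", ""),
                                                NA, col)))
      if (all(is.na(num) == (col %in% c("na", "NA", "")))) {
        df[[cn]] <- num
      } else {
        stop(sprintf("parse error in %s, column '%s': non-numeric values",
                     path, cn), call. = FALSE)
      }
    }
  }
  df
}

#' @rdname read_assay_table
#' @param df data.frame to write.
#' @return `write_assay_table`: the path, invisibly.
#' @export
write_assay_table <- function(df, path, schema = names(.assay_schemas)) {
  schema <- match.arg(schema)
  want <- .assay_schemas[[schema]]
  if (!is.null(want)) {
    missing_cols <- setdiff(want, names(df))
    if (length(missing_cols))
      stop(sprintf("schema '%s' mismatch: missing columns %s", schema,
                   paste(missing_cols, collapse = ", ")), call. = FALSE)
  } else if (!"compound" %in% names(df)) {
    stop(sprintf("schema '%s' mismatch: missing column compound", schema),
         call. = FALSE)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a current trace as CSV plus JSON metadata sidecar
#'
#' @param trace A `"current_trace"`.
#' @param path CSV path; the sidecar is written next to it with a `.json`
#'   extension.
#' @return The CSV path, invisibly.
#' @export
write_trace <- function(trace, path) {
  write_assay_table(data.frame(time_s = trace$time,
                               current_pA = trace$current),
                    path, schema = "trace")
  meta <- list(voltage_mV = trace$voltage,
               sampling_hz = trace$sampling_rate,
               filter_hz = trace$filter_cutoff,
               temperature_K = trace$temperature,
               seed = trace$model$seed,
               true_parameters = trace$model[c("open_rate", "close_rate",
                                               "unit_current",
                                               "baseline_current",
                                               "noise_sd", "duration")])
  jsonlite::write_json(meta, sub("\\.csv$", ".json", path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a current trace written by [write_trace()]
#' @param path CSV path (sidecar expected alongside).
#' @return A `"current_trace"`.
#' @export
read_trace <- function(path) {
  df <- read_assay_table(path, "trace")
  meta_path <- sub("\\.csv$", ".json", path)
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  dt <- diff(df$time_s)
  fs <- meta$sampling_hz %||% (1 / stats::median(dt))
  structure(list(time = df$time_s, current = df$current_pA,
                 voltage = meta$voltage_mV %||% NA_real_,
                 sampling_rate = fs,
                 filter_cutoff = meta$filter_hz,
                 temperature = meta$temperature_K %||% 298.15,
                 true_events = NULL, model = NULL),
            class = "current_trace")
}
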