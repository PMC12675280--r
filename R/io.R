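# Table schemas for the delimited-text interfaces. Each schema names the
# required columns, their kinds, and an optional unique-id column.
table_schemas <- list(
  stream = list(cols = c(time_s = "numeric", value = "numeric")),
  counts = list(cols = c(region_id = "integer", subject_id = "character",
                         count = "integer")),
  subjects = list(cols = c(subject_id = "character", group = "character"),
                  unique = "subject_id"),
  cells = list(cols = c(cell_id = "character", sample_id = "character",
                        condition = "character"),
               unique = "cell_id", extra = "numeric"),
  trace = list(cols = c(channel_id = "character", time_s = "numeric",
                        value = "numeric"))
)

convert_column <- function(x, kind, col, path) {
  if (kind == "character") return(as.character(x))
  suppressWarnings(num <- as.numeric(x))
  bad <- which(!is.na(x) & is.na(num))
  if (length(bad)) {
    abort(sprintf("%s: column '%s' has a non-numeric value at row %d ('%s').",
                  path, col, bad[1], x[bad[1]]), class = "gliatrace_data_error")
  }
  if (kind == "integer") {
    frac <- which(!is.na(num) & num != floor(num))
    if (length(frac)) {
      abort(sprintf("%s: column '%s' must be integral; row %d has '%s'.",
                    path, col, frac[1], x[frac[1]]),
            class = "gliatrace_data_error")
    }
    return(as.integer(num))
  }
  num
}

#' Load and validate a delimited-text table
#'
#' Reads a comma-separated table with a header and validates it against a
#' named schema: missing columns are reported by name, non-numeric or
#' non-integral values by row, and duplicated ids rejected. Columns not in
#' the schema are kept (converted to numeric for schemas that expect
#' extra numeric columns, e.g. per-gene intensities).
#'
#' @param path File path.
#' @param schema_id One of `"stream"`, `"counts"`, `"subjects"`,
#'   `"cells"`, `"trace"`.
#' @return A validated tibble.
#' @export
load_table <- function(path, schema_id) {
  if (!schema_id %in% names(table_schemas)) {
    abort(sprintf("Unknown schema '%s'.", schema_id))
  }
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "gliatrace_user_error")
  }
  schema <- table_schemas[[schema_id]]
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  missing <- setdiff(names(schema$cols), names(raw))
  if (length(missing)) {
    abort(sprintf("%s: missing required column(s): %s", path,
                  paste(missing, collapse = ", ")),
          class = "gliatrace_data_error")
  }
  out <- raw
  for (col in names(schema$cols)) {
    out[[col]] <- convert_column(raw[[col]], schema$cols[[col]], col, path)
  }
  extra_kind <- schema$extra %||% NULL
  if (!is.null(extra_kind)) {
    for (col in setdiff(names(raw), names(schema$cols))) {
      out[[col]] <- convert_column(raw[[col]], extra_kind, col, path)
    }
  }
  if (!is.null(schema$unique) && anyDuplicated(out[[schema$unique]])) {
    dup <- out[[schema$unique]][duplicated(out[[schema$unique]])][1]
    abort(sprintf("%s: duplicate %s '%s'.", path, schema$unique, dup),
          class = "gliatrace_data_error")
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a table deterministically
#'
#' Writes a comma-separated file with a fixed column order, rows sorted by
#' the first id-like column, and numeric columns rounded to 6 significant
#' digits, so re-running on the same input is byte-identical.
#'
#' @param x Data frame.
#' @param path Output path (directories are created).
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  x <- as.data.frame(x)
  id_col <- intersect(c("region_id", "cell_id", "subject_id", "sample_id",
                        "time_s", "start_s"), names(x))
  if (length(id_col)) {
    ord <- do.call(order, x[, id_col, drop = FALSE])
    x <- x[ord, , drop = FALSE]
  }
  for (col in names(x)) {
    if (is.double(x[[col]])) x[[col]] <- signif(x[[col]], 6)
  }
  readr::write_csv(tibble::as_tibble(x), path, progress = FALSE)
  invisible(path)
}

#' Write a set of result tables to a directory
#'
#' @param results Named list of data frames; each is written as
#'   `<name>.csv` via [write_table()].
#' @param out_dir Output directory.
#' @return Character vector of the written paths, invisibly.
#' @export
write_report <- function(results, out_dir) {
  if (is.null(names(results)) || any(!nzchar(names(results)))) {
    abort("`results` must be a fully named list.")
  }
  paths <- vapply(names(results), function(nm) {
    write_table(results[[nm]], file.path(out_dir, paste0(nm, ".csv")))
  }, character(1))
  invisible(unname(paths))
}

#' Read or write a region ontology as structured text
#'
#' The ontology is stored as a JSON array of records with fields `id`,
#' `acronym`, `name`, `parent_id`, `size_mm3`, `is_ventricular`,
#' `is_aggregate`.
#'
#' @param ontology Ontology tibble.
#' @param path File path.
#' @return `read_ontology()` returns the validated tibble;
#'   `write_ontology()` returns `path` invisibly.
#' @export
write_ontology <- function(ontology, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(ontology, path, dataframe = "rows", na = "null",
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_ontology
#' @export
read_ontology <- function(path) {
  ont <- tibble::as_tibble(jsonlite::fromJSON(path))
  need <- c("id", "acronym", "name", "size_mm3", "is_ventricular",
            "is_aggregate")
  missing <- setdiff(need, names(ont))
  if (length(missing)) {
    abort(sprintf("%s: ontology missing field(s): %s", path,
                  paste(missing, collapse = ", ")),
          class = "gliatrace_data_error")
  }
  if (!"parent_id" %in% names(ont)) ont$parent_id <- NA_integer_
  if (anyDuplicated(ont$id)) {
    abort(sprintf("%s: duplicate ontology ids.", path),
          class = "gliatrace_data_error")
  }
  if (any(ont$size_mm3 <= 0)) {
    abort(sprintf("%s: ontology sizes must be positive.", path),
          class = "gliatrace_data_error")
  }
  ont
}

#' Read or write a ground-truth record as structured text
#'
#' @param truth A list of ground-truth parameters (as emitted by the
#'   generators).
#' @param path File path.
#' @return `read_truth()` returns the list; `write_truth()` returns
#'   `path` invisibly.
#' @export
write_truth <- function(truth, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(truth, path, dataframe = "rows", na = "null",
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
}
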