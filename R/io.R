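# CSV interfaces. One convention everywhere: UTF-8, header row, empty field
# means missing, dates in ISO-8601. A deidentified file must never carry
# identifier columns; validate_schema() enforces that guard at every
# boundary.

.schemas <- list(
  identified = c("record_id", "site_id", "site_type", "first_name",
                 "last_name", "birth_day", "birth_month", "birth_year",
                 "sex", "postcode", "medicare_number"),
  deid = c("record_id", "site_id", "site_type", "key1", "key2", "key3",
           "key4", "sex", "birth_year"),
  links = c("record_id", "link_id", "approach"),
  pairs = c("record_id_a", "record_id_b", "matched_types"),
  gold = c("record_id", "gold_id"),
  registry = c("person_id", "record_id"),
  tests = c("record_id", "analyte", "result", "test_date", "specimen_id")
)

# identifier columns that must never appear after deidentification
.identifier_cols <- c("first_name", "last_name", "birth_day", "birth_month",
                      "postcode", "medicare_number")

#' Validate a CSV file against a pipeline schema
#'
#' Checks the header names and, for deidentified schemas, that no identifier
#' column leaks through. Returns a character vector of violations (empty =
#' valid).
#'
#' @param file Path to a CSV file.
#' @param schema One of `"identified"`, `"deid"`, `"links"`, `"pairs"`,
#'   `"gold"`, `"registry"`, `"tests"`.
#' @return Character vector of violation messages; `character(0)` if the file
#'   conforms.
#' @export
validate_schema <- function(file, schema = names(.schemas)) {
  schema <- match.arg(schema)
  if (!file.exists(file)) stop("cannot read file: ", file)
  header <- names(utils::read.csv(file, nrows = 1, check.names = FALSE))
  expected <- .schemas[[schema]]
  out <- character(0)
  miss <- setdiff(expected, header)
  if (length(miss)) {
    out <- c(out, paste0("missing column(s): ", paste(miss, collapse = ", ")))
  }
  extra <- setdiff(header, expected)
  if (length(extra)) {
    out <- c(out, paste0("unexpected column(s): ",
                         paste(extra, collapse = ", ")))
  }
  if (schema != "identified") {
    leak <- intersect(header, .identifier_cols)
    if (length(leak)) {
      out <- c(out, paste0("identifier column(s) forbidden after ",
                           "deidentification: ", paste(leak, collapse = ", ")))
    }
  }
  out
}

#' Read a pipeline CSV
#'
#' Reads with the package conventions (empty string = missing, no factor
#' coercion) and errors if the header does not match the schema.
#'
#' @inheritParams validate_schema
#' @return A data.frame.
#' @export
read_linkage_csv <- function(file, schema = names(.schemas)) {
  schema <- match.arg(schema)
  violations <- validate_schema(file, schema)
  if (length(violations)) {
    stop("schema violations in ", file, ":\n  ",
         paste(violations, collapse = "\n  "))
  }
  df <- utils::read.csv(file, stringsAsFactors = FALSE,
                        colClasses = "character", na.strings = "")
  int_cols <- intersect(names(df), c("birth_day", "birth_month", "birth_year"))
  for (cc in int_cols) df[[cc]] <- suppressWarnings(as.integer(df[[cc]]))
  if ("test_date" %in% names(df)) df$test_date <- as.Date(df$test_date)
  df
}

#' Write a pipeline CSV
#'
#' @param df Data.frame to write.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_linkage_csv <- function(df, file) {
  df <- as.data.frame(df)
  for (cc in names(df)) {
    if (inherits(df[[cc]], "Date")) df[[cc]] <- format(df[[cc]], "%Y-%m-%d")
  }
  utils::write.csv(df, file, row.names = FALSE, na = "")
  invisible(file)
}

#' Write a run manifest
#'
#' Records the inputs, seeds, package version and row counts of a pipeline
#' stage, sufficient to reproduce the run bit-identically. The secret seed is
#' never included.
#'
#' @param path Output JSON path.
#' @param stage Stage name.
#' @param inputs Named list of input file paths.
#' @param outputs Named list of output file paths.
#' @param params Named list of non-secret parameters (seeds, approach,
#'   windows).
#' @param counts Named list of row counts.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, stage, inputs = list(), outputs = list(),
                           params = list(), counts = list()) {
  stopifnot(!("secret_seed" %in% names(params)))
  manifest <- list(
    stage = stage,
    package = "hashlink",
    version = as.character(utils::packageVersion("hashlink")),
    inputs = inputs, outputs = outputs, params = params, counts = counts
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
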