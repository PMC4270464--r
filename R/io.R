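# Typed CSV readers/writers for every table the pipeline consumes. Each
# schema names its columns and types; readers fail loudly, naming the
# missing column or the location of a malformed cell.

#' Table schemas used by the pipeline
#'
#' A named list of schemas; each entry gives the required column names and
#' their readr type (`c` = character, `d` = double). Schemas:
#' `elutriation`, `histogram`, `decay`, `uptake`, `aa_panel`, `lifespan`,
#' `strains`.
#'
#' @return A named list of named character vectors (column name -> type).
#' @export
g1span_schemas <- function() {
  list(
    elutriation = c(label = "c", time_h = "d", mean_volume_fl = "d",
                    budded_fraction = "d"),
    histogram = c(label = "c", bin_left_fl = "d", bin_right_fl = "d",
                  count = "d"),
    decay = c(label = "c", time_min = "d", target_density = "d",
              loading_density = "d"),
    uptake = c(condition = "c", time_min = "d", counts = "d"),
    aa_panel = c(amino_acid = "c", replicate = "d", control_nmol = "d",
                 treated_nmol = "d"),
    lifespan = c(group = "c", lifespan = "d", event = "d"),
    strains = c(strain_id = "c", fitness = "d", mean_size_fl = "d",
                birth_size_fl = "d", g1_dna_fraction = "d", rls_class = "c")
  )
}

get_schema <- function(schema) {
  schemas <- g1span_schemas()
  if (!schema %in% names(schemas)) {
    abort(sprintf("unknown schema '%s'; available: %s.", schema,
                  paste(names(schemas), collapse = ", ")),
          class = "g1span_schema_error")
  }
  schemas[[schema]]
}

#' Read a typed pipeline table from CSV
#'
#' @param path Path to a CSV file.
#' @param schema Schema name (see [g1span_schemas()]).
#' @return A tibble with the schema's columns, typed; extra columns are
#'   kept as read.
#' @export
read_g1span_table <- function(path, schema) {
  sch <- get_schema(schema)
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "g1span_io_error")
  }
  header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE,
                                  progress = FALSE))
  missing <- setdiff(names(sch), header)
  if (length(missing) > 0) {
    abort(sprintf("%s: missing required column(s): %s.", path,
                  paste(missing, collapse = ", ")),
          class = "g1span_schema_error")
  }
  types <- do.call(readr::cols, as.list(sch))
  # parsing problems are re-raised as errors below; silence readr's own note
  out <- suppressWarnings(readr::read_csv(path, col_types = types,
                                          progress = FALSE))
  probs <- readr::problems(out)
  if (nrow(probs) > 0) {
    first <- probs[1, ]
    abort(sprintf(
      "%s: %d malformed cell(s); first at row %d, column %d (expected %s, got '%s').",
      path, nrow(probs), first$row, first$col, first$expected, first$actual),
      class = "g1span_parse_error")
  }
  out
}

#' Write a pipeline table to CSV
#'
#' @param data A tibble with at least the schema's columns.
#' @param path Output CSV path.
#' @param schema Schema name (see [g1span_schemas()]).
#' @return `path`, invisibly.
#' @export
write_g1span_table <- function(data, path, schema) {
  sch <- get_schema(schema)
  check_columns(data, names(sch), "`data`")
  readr::write_csv(data[names(sch)], path, progress = FALSE)
  invisible(path)
}
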