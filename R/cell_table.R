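#' Assemble a single-cell output concentration table
#'
#' A cell table holds one row per cell: an experimental condition (the pair of
#' input concentration and exposure time) plus one column per measured output
#' molecule, on the linear concentration scale (arbitrary fluorescence units).
#' It is the raw material for all Gaussian fits: downstream analyses work on
#' the natural logarithm of the output columns, so every output value must be
#' strictly positive.
#'
#' @param condition_id character vector of condition labels, one per cell.
#' @param input_level numeric vector, input concentration (e.g. TNF in ng/mL).
#' @param timepoint numeric vector, exposure time in minutes.
#' @param outputs data frame or named list of numeric vectors, one entry per
#'   output molecule, linear-scale concentrations.
#' @return A `cell_table`: a tibble with columns `condition_id`, `input_level`,
#'   `timepoint` and one column per output, carrying attributes `outputs`
#'   (character vector of output column names) and `n_excluded`.
#' @seealso [read_cell_table()], [write_cell_table()], [log_transform()]
#' @export
cell_table <- function(condition_id, input_level, timepoint, outputs) {
  outputs <- tibble::as_tibble(outputs)
  if (ncol(outputs) < 1L) stop("at least one output column is required")
  tab <- tibble::tibble(
    condition_id = as.character(condition_id),
    input_level = as.numeric(input_level),
    timepoint = as.numeric(timepoint)
  )
  tab <- tibble::as_tibble(cbind(tab, outputs))
  new_cell_table(tab, names(outputs), n_excluded = 0L)
}

new_cell_table <- function(tab, output_names, n_excluded = 0L) {
  bad <- vapply(tab[output_names],
                function(v) any(!is.finite(v) | v <= 0), logical(1))
  if (any(bad)) {
    stop("nonpositive or missing concentration in output(s): ",
         paste(output_names[bad], collapse = ", "))
  }
  structure(tab,
            outputs = output_names,
            n_excluded = as.integer(n_excluded),
            class = c("cell_table", class(tab)))
}

#' @export
print.cell_table <- function(x, ...) {
  cat(sprintf("<cell_table> %d cells, %d conditions, outputs: %s (%d rows excluded at read)\n",
              nrow(x), length(unique(x$condition_id)),
              paste(attr(x, "outputs"), collapse = ", "),
              attr(x, "n_excluded")))
  NextMethod()
}

#' Names of the measured output molecules
#' @param table a `cell_table`.
#' @return character vector of output column names.
#' @export
output_names <- function(table) attr(table, "outputs")

#' Read a delimited single-cell concentration table
#'
#' Reads a comma- or tab-delimited text file (dialect auto-detected from the
#' header line) with one row per cell. Rows with missing or nonpositive output
#' values are excluded — the log transform is undefined there — and the
#' exclusion count is reported via a message and stored in the `n_excluded`
#' attribute.
#'
#' @param path path to a delimited text file with a header.
#' @param schema named list mapping table roles to column names:
#'   `condition` (optional; synthesized from input level and timepoint if
#'   absent), `input_level`, `timepoint`, and `outputs` (character vector of
#'   output columns, optionally named to rename them; `NULL` means all
#'   remaining columns).
#' @return A [cell_table()].
#' @export
read_cell_table <- function(path,
                            schema = list(condition = "condition_id",
                                          input_level = "input_level",
                                          timepoint = "timepoint",
                                          outputs = NULL)) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           fileEncoding = "UTF-8")
  for (role in c("input_level", "timepoint")) {
    col <- schema[[role]]
    if (is.null(col) || !col %in% names(raw)) {
      stop("schema error: required column for '", role, "' (",
           if (is.null(col)) "<unset>" else col, ") not found in header")
    }
  }
  out_cols <- schema$outputs
  if (is.null(out_cols)) {
    taken <- unlist(schema[c("condition", "input_level", "timepoint")])
    out_cols <- setdiff(names(raw), taken)
    names(out_cols) <- out_cols
  }
  if (length(out_cols) < 1L) stop("schema error: no output columns")
  missing_out <- setdiff(unname(out_cols), names(raw))
  if (length(missing_out) > 0L) {
    stop("schema error: output column(s) not found: ",
         paste(missing_out, collapse = ", "))
  }
  if (is.null(names(out_cols))) names(out_cols) <- out_cols

  outputs <- raw[unname(out_cols)]
  names(outputs) <- names(out_cols)
  outputs[] <- lapply(outputs, as.numeric)
  usable <- Reduce(`&`, lapply(outputs, function(v) is.finite(v) & v > 0))
  n_excluded <- sum(!usable)
  if (sum(usable) == 0L) stop("no usable rows after excluding nonpositive/missing outputs")
  if (n_excluded > 0L) {
    message(n_excluded, " row(s) excluded (missing or nonpositive output values)")
  }

  cond_col <- schema$condition
  input_level <- as.numeric(raw[[schema$input_level]])[usable]
  timepoint <- as.numeric(raw[[schema$timepoint]])[usable]
  condition_id <- if (!is.null(cond_col) && cond_col %in% names(raw)) {
    as.character(raw[[cond_col]])[usable]
  } else {
    condition_label(input_level, timepoint)
  }
  tab <- cell_table(condition_id, input_level, timepoint,
                    outputs[usable, , drop = FALSE])
  attr(tab, "n_excluded") <- as.integer(n_excluded)
  tab
}

condition_label <- function(input_level, timepoint) {
  sprintf("tnf%g_t%g", input_level, timepoint)
}

#' Write a cell table to delimited text
#'
#' Numeric values are written with 17 significant digits so a write/read
#' round trip reproduces the table to within 1e-12.
#'
#' @param table a `cell_table`.
#' @param path output path; a `.tsv` extension selects tab separation,
#'   anything else comma.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(table, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- as.data.frame(table)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  utils::write.table(df, path, sep = sep, quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Log-transform selected outputs, grouped by condition
#'
#' Applies the natural logarithm elementwise to the selected output columns —
#' the analysis models x = ln(concentration) as Gaussian — and splits the
#' result by condition.
#'
#' @param table a `cell_table`.
#' @param outputs character vector of output names; defaults to all outputs.
#' @return Named list (one element per condition label, in order of first
#'   appearance) of numeric matrices, cells in rows and the requested outputs
#'   in columns.
#' @export
log_transform <- function(table, outputs = output_names(table)) {
  missing_out <- setdiff(outputs, output_names(table))
  if (length(missing_out) > 0L) {
    stop("unknown output(s): ", paste(missing_out, collapse = ", "))
  }
  m <- as.matrix(as.data.frame(table)[outputs])
  if (any(!is.finite(m) | m <= 0)) {
    stop("internal invariant violation: nonpositive concentration reached log_transform")
  }
  m <- log(m)
  colnames(m) <- outputs
  conds <- unique(table$condition_id)
  out <- lapply(conds, function(cc) m[table$condition_id == cc, , drop = FALSE])
  names(out) <- conds
  out
}

#' Slice a cell table by experimental condition
#'
#' A condition is the pair (input level, timepoint); hypotheses are declared
#' over the input level at a fixed timepoint.
#'
#' @param table a `cell_table`.
#' @param input_level input concentration to select.
#' @param timepoint exposure time (minutes) to select.
#' @return A `cell_table` restricted to the matching cells.
#' @export
condition_slice <- function(table, input_level, timepoint) {
  keep <- table$input_level == input_level & table$timepoint == timepoint
  if (!any(keep)) {
    avail <- unique(paste0(table$input_level, " ng/mL @ ", table$timepoint, " min"))
    stop("no cells at input level ", input_level, ", timepoint ", timepoint,
         "; available conditions: ", paste(avail, collapse = "; "))
  }
  out <- table[keep, ]
  new_cell_table(out, output_names(table), attr(table, "n_excluded"))
}
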