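#' Column schema for a compound descriptor table
#'
#' Describes the columns expected in a descriptor table: the identity column,
#' the molecular descriptors with their units, and the response columns.
#' The default schema matches the packaged 65-compound reference dataset:
#' the micellar lipophilicity descriptor log(km/KAM), topological polar
#' surface area (TPSA, A^2), hydrogen-bond donor/acceptor counts (HBD, HBA),
#' number of rotatable bonds (NRB), molecular weight (MW, g/mol),
#' polarizability (alpha, A^3), parachor (P, m^3/mol), and the two
#' blood-brain partitioning responses log BB and log BB*.
#'
#' @param required Character vector of column names that must be present.
#'   Defaults to all columns of the packaged schema.
#' @return A data frame with columns `name`, `units`, `role`
#'   (one of `"identity"`, `"descriptor"`, `"response"`) and `integer`
#'   (logical: count-valued descriptor).
#' @export
descriptor_schema <- function(required = NULL) {
  sch <- data.frame(
    name = c("compound_id", "log_km_kam", "log_bb", "log_bb_star",
             "tpsa", "hbd", "hba", "nrb", "mw", "alpha", "parachor_P"),
    units = c("", "", "", "", "A^2", "count", "count", "count",
              "g mol^-1", "A^3", "m^3 mol^-1"),
    role = c("identity", "descriptor", "response", "response",
             "descriptor", "descriptor", "descriptor", "descriptor",
             "descriptor", "descriptor", "descriptor"),
    integer = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE,
                FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
  if (!is.null(required)) {
    missing <- setdiff(required, sch$name)
    if (length(missing))
      stop("unknown schema column(s): ", paste(missing, collapse = ", "))
    sch <- sch[sch$name %in% c("compound_id", required), , drop = FALSE]
  }
  sch
}

# Read a delimited text file tolerating the typographic minus sign used in
# printed tables; returns the raw character grid plus header.
read_normalized_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- gsub("−", "-", lines)   # Unicode minus -> ASCII hyphen-minus
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1L)
    stop("schema error: file is empty: ", path)
  utils::read.csv(text = paste(lines, collapse = "\n"),
                  stringsAsFactors = FALSE, check.names = FALSE,
                  colClasses = "character")
}

parse_numeric_column <- function(x, column) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x) & nzchar(trimws(x)))
  if (length(bad))
    stop(sprintf("parse error: non-numeric value '%s' in column '%s', row %d",
                 x[bad[1]], column, bad[1]))
  out
}

#' Load a compound descriptor table
#'
#' Reads a comma-delimited descriptor table (UTF-8, header row) into a
#' validated `descriptor_table`. The typographic minus sign (U+2212) is
#' accepted as a negative sign. Count-valued descriptors (HBD, HBA, NRB)
#' must be non-negative integers and compound identifiers must be unique.
#'
#' @param path Path to a CSV file.
#' @param schema Column metadata as returned by [descriptor_schema()].
#'   Every schema column must be present in the file; extra file columns
#'   are kept as-is.
#' @return A data frame of class `descriptor_table` with one row per
#'   compound and attributes `schema` (the column metadata).
#' @seealso [bbb_compounds()] for the packaged reference table.
#' @export
load_descriptor_table <- function(path, schema = descriptor_schema()) {
  raw <- read_normalized_csv(path)
  if (nrow(raw) == 0L)
    stop("schema error: no data rows in ", path)
  missing <- setdiff(schema$name, names(raw))
  if (length(missing))
    stop("schema error: missing column(s): ", paste(missing, collapse = ", "))
  out <- raw
  for (j in seq_len(nrow(schema))) {
    nm <- schema$name[j]
    if (schema$role[j] == "identity") next
    out[[nm]] <- parse_numeric_column(raw[[nm]], nm)
    if (any(!is.finite(out[[nm]])))
      stop("validation error: non-finite value in column '", nm, "'")
    if (isTRUE(schema$integer[j])) {
      v <- out[[nm]]
      if (any(v < 0) || any(v != round(v)))
        stop("validation error: column '", nm,
             "' must contain non-negative integers")
    }
  }
  if (anyDuplicated(out$compound_id))
    stop("validation error: duplicate compound_id: ",
         paste(unique(out$compound_id[duplicated(out$compound_id)]),
               collapse = ", "))
  rownames(out) <- NULL
  structure(out, schema = schema,
            class = c("descriptor_table", "data.frame"))
}

#' Load a table of per-compound Foley fit parameters
#'
#' Reads a CSV with columns `compound_id`, `inv_km` (intercept 1/km),
#' `kam_over_km` (slope KAM/km, L/mol) and `r2` (coefficient of
#' determination of the 1/k vs \[M\] straight line). Rows with missing
#' values are skipped with a warning; an r2 outside \[0, 1\] is an error.
#'
#' @param path Path to a CSV file.
#' @return A data frame with the four columns above, one row per compound.
#' @seealso [bbb_foley_parameters()] for the packaged reference table.
#' @export
load_foley_table <- function(path) {
  raw <- read_normalized_csv(path)
  need <- c("compound_id", "inv_km", "kam_over_km", "r2")
  missing <- setdiff(need, names(raw))
  if (length(missing))
    stop("schema error: missing column(s): ", paste(missing, collapse = ", "))
  out <- raw[need]
  for (nm in c("inv_km", "kam_over_km", "r2"))
    out[[nm]] <- parse_numeric_column(raw[[nm]], nm)
  incomplete <- !stats::complete.cases(out)
  if (any(incomplete)) {
    warning(sum(incomplete), " row(s) with missing values skipped")
    out <- out[!incomplete, , drop = FALSE]
  }
  if (any(out$r2 < 0 | out$r2 > 1))
    stop("validation error: r2 outside [0, 1] for compound(s): ",
         paste(out$compound_id[out$r2 < 0 | out$r2 > 1], collapse = ", "))
  rownames(out) <- NULL
  out
}

#' Packaged 65-compound reference tables
#'
#' `bbb_compounds()` returns the descriptor table for the 65 heterocyclic
#' drug-like compounds (micellar lipophilicity descriptor, in-silico
#' descriptors, and the log BB / log BB* responses). `bbb_foley_parameters()`
#' returns their per-compound Foley fit parameters (intercept 1/km, slope
#' KAM/km, and fit R^2) determined over SDS concentrations
#' 0.10-0.12 mol/L.
#'
#' @return `bbb_compounds()`: a `descriptor_table` with 65 rows;
#'   `bbb_foley_parameters()`: a data frame with 65 rows.
#' @export
bbb_compounds <- function() {
  load_descriptor_table(system.file("extdata", "compound_descriptors.csv",
                                    package = "mlcqsar", mustWork = TRUE))
}

#' @rdname bbb_compounds
#' @export
bbb_foley_parameters <- function() {
  load_foley_table(system.file("extdata", "foley_parameters.csv",
                               package = "mlcqsar", mustWork = TRUE))
}

#' Write a model validation report
#'
#' Writes one row per model with the full validation battery: R^2, adjusted
#' and predicted R^2, leave-one-out PRESS, maximum VIF, total sum of squares
#' SS, MSE, F, p-value, Q^2(LOO) and PRESS(LOO). R-type statistics are
#' formatted to 4 decimals in the CSV output; `format = "text"` writes an
#' aligned fixed-width table instead.
#'
#' @param stats A list of `model_stats` objects (see [model_statistics()]).
#' @param path Output file path.
#' @param format `"csv"` (default) or `"text"`.
#' @return Invisibly, the formatted data frame that was written.
#' @export
write_model_report <- function(stats, path, format = c("csv", "text")) {
  format <- match.arg(format)
  if (inherits(stats, "model_stats")) stats <- list(stats)
  if (!length(stats)) stop("empty model statistics collection")
  rows <- lapply(stats, function(s) {
    stopifnot(inherits(s, "model_stats"))
    data.frame(
      model = s$label,
      R2 = sprintf("%.4f", s$r2),
      R2_adj = sprintf("%.4f", s$r2_adj),
      R2_pred = sprintf("%.4f", s$r2_pred),
      PRESS = sprintf("%.4f", s$press),
      max_VIF = sprintf("%.1f", s$max_vif),
      SS = sprintf("%.4f", s$ss),
      MSE = sprintf("%.4f", s$mse),
      F = if (is.finite(s$f)) sprintf("%.1f", s$f) else "Inf",
      p = sprintf("%.5f", s$p_value),
      Q2_LOO = sprintf("%.4f", s$q2_loo),
      PRESS_LOO = sprintf("%.4f", s$press_loo),
      stringsAsFactors = FALSE
    )
  })
  report <- do.call(rbind, rows)
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) stop("I/O error: cannot write ", path))
  on.exit(close(con))
  if (format == "csv") {
    utils::write.csv(report, con, row.names = FALSE, quote = FALSE)
  } else {
    widths <- pmax(nchar(names(report)),
                   apply(report, 2, function(x) max(nchar(x))))
    fmt_row <- function(x) paste(mapply(formatC, x, width = widths),
                                 collapse = "  ")
    writeLines(c(fmt_row(names(report)),
                 apply(report, 1, fmt_row)), con)
  }
  invisible(report)
}
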