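#' Variable metadata
#'
#' Describes a single column of a mixed-type clinical table: its name, its
#' measurement kind, the admissible levels (for nominal kinds) and its role
#' in the analysis.
#'
#' @param name Column name (single string).
#' @param kind One of `"binary"`, `"ordinal"`, `"categorical"`, `"continuous"`.
#' @param levels Ordered character vector of admissible values.  Required for
#'   binary/ordinal/categorical variables (binary must have exactly 2);
#'   must be absent for continuous variables.  For ordinal variables the order
#'   of `levels` is the level order used by quantification.
#' @param role One of `"feature"`, `"outcome"`, `"annotation"`.  Only features
#'   enter the numeric data space; outcomes and annotations are carried along
#'   for association and survival analysis.
#' @return An object of class `variable_meta`.
#' @export
variable_meta <- function(name, kind, levels = NULL,
                          role = c("feature", "outcome", "annotation")) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  kind <- match.arg(kind, c("binary", "ordinal", "categorical", "continuous"))
  role <- match.arg(role)
  if (kind == "continuous") {
    if (!is.null(levels) && length(levels))
      stopf("variable '%s': continuous variables take no levels", name)
    levels <- NULL
  } else {
    if (is.null(levels) || length(levels) < 1L)
      stopf("variable '%s': kind '%s' requires declared levels", name, kind)
    levels <- as.character(levels)
    if (anyDuplicated(levels))
      stopf("variable '%s': duplicated levels", name)
    if (kind == "binary" && length(levels) != 2L)
      stopf("variable '%s': binary variables need exactly 2 levels, got %d",
            name, length(levels))
  }
  structure(list(name = name, kind = kind, levels = levels, role = role),
            class = "variable_meta")
}

#' @export
print.variable_meta <- function(x, ...) {
  lv <- if (is.null(x$levels)) "" else
    paste0(" {", paste(x$levels, collapse = ", "), "}")
  cat(sprintf("<variable_meta> %s: %s%s [%s]\n", x$name, x$kind, lv, x$role))
  invisible(x)
}

#' Mixed-type dataset
#'
#' The universal input container: an observation-by-variable table whose
#' columns may be binary, ordinal, categorical or continuous, together with a
#' missingness mask and per-variable metadata.  Nominal entries are stored as
#' character strings and validated against the declared levels; continuous
#' entries are numeric.
#'
#' @param values A data.frame (observations in rows).  `NA` marks missing.
#' @param meta A list of [variable_meta()] objects, one per column of
#'   `values`, in column order or matched by name.
#' @param row_ids Optional character vector of observation identifiers;
#'   defaults to the row names of `values` or `"1"..."n"`.
#' @return An object of class `mixed_dataset` with elements `values`,
#'   `missing_mask`, `meta`, `row_ids`.
#' @export
mixed_dataset <- function(values, meta, row_ids = NULL) {
  stopifnot(is.data.frame(values))
  if (inherits(meta, "variable_meta")) meta <- list(meta)
  names(meta) <- vapply(meta, `[[`, character(1), "name")
  if (length(meta) != ncol(values))
    stopf("metadata declares %d variables but the table has %d columns",
          length(meta), ncol(values))
  if (!setequal(names(meta), colnames(values)))
    stopf("undeclared or missing columns: table has [%s], metadata declares [%s]",
          paste(setdiff(colnames(values), names(meta)), collapse = ", "),
          paste(setdiff(names(meta), colnames(values)), collapse = ", "))
  meta <- meta[colnames(values)]
  if (is.null(row_ids)) {
    row_ids <- rownames(values) %||% as.character(seq_len(nrow(values)))
  }
  row_ids <- as.character(row_ids)
  stopifnot(length(row_ids) == nrow(values))

  # validate and normalize column storage
  for (j in seq_along(meta)) {
    m <- meta[[j]]
    col <- values[[j]]
    if (m$kind == "continuous") {
      if (!is.numeric(col)) {
        suppressWarnings(num <- as.numeric(as.character(col)))
        bad <- which(!is.na(col) & is.na(num))
        if (length(bad))
          stopf("column '%s': non-numeric entry '%s' at row %s for a continuous variable",
                m$name, as.character(col[bad[1]]), row_ids[bad[1]])
        col <- num
      }
    } else {
      col <- as.character(col)
      bad <- which(!is.na(col) & !(col %in% m$levels))
      if (length(bad))
        stopf("column '%s': entry '%s' at row %s is not among declared levels {%s}",
              m$name, col[bad[1]], row_ids[bad[1]],
              paste(m$levels, collapse = ", "))
    }
    values[[j]] <- col
  }
  mask <- is.na(as.matrix(values))
  dimnames(mask) <- list(row_ids, colnames(values))
  rownames(values) <- row_ids
  structure(list(values = values, missing_mask = mask, meta = meta,
                 row_ids = row_ids),
            class = "mixed_dataset")
}

#' @export
print.mixed_dataset <- function(x, ...) {
  kinds <- table(vapply(x$meta, `[[`, character(1), "kind"))
  cat(sprintf("<mixed_dataset> %d observations x %d variables (%s); %.1f%% missing\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%d %s", kinds, names(kinds)), collapse = ", "),
              100 * mean(x$missing_mask)))
  invisible(x)
}

#' @export
dim.mixed_dataset <- function(x) dim(x$values)

#' Default tokens interpreted as missing when reading delimited text
#' @export
default_missing_tokens <- function() c("", "NA", "NaN", "?")

#' Read a mixed-type dataset from delimited text plus a metadata sidecar
#'
#' The table must be comma- or tab-delimited (autodetected from the header
#' line) with a header row; the sidecar is a JSON array of objects with
#' fields `name`, `kind`, `levels` (omitted for continuous) and `role`.
#' Every column of the table must be declared in the sidecar.
#'
#' @param table_path Path to the delimited table.
#' @param meta_path Path to the JSON metadata sidecar.
#' @param missing_tokens Strings read as missing entries.
#' @return A [mixed_dataset()].
#' @export
read_dataset <- function(table_path, meta_path,
                         missing_tokens = default_missing_tokens()) {
  meta <- read_variable_meta(meta_path)
  header <- readLines(table_path, n = 1L)
  if (!length(header) || !nzchar(header))
    stopf("'%s': empty file or missing header line", table_path)
  sep <- if (lengths(regmatches(header, gregexpr("\t", header))) > 0) "\t" else ","
  df <- utils::read.table(table_path, header = TRUE, sep = sep,
                          colClasses = "character", na.strings = NULL,
                          check.names = FALSE, quote = "\"",
                          fileEncoding = "UTF-8", comment.char = "")
  if (!ncol(df)) stopf("'%s': missing header", table_path)
  for (j in seq_along(df)) df[[j]][df[[j]] %in% missing_tokens] <- NA_character_
  mixed_dataset(df, meta)
}

#' Read a variable-metadata sidecar (JSON)
#' @param meta_path Path to a JSON array of
#'   `{name, kind, levels, role}` objects.
#' @return List of [variable_meta()] objects.
#' @export
read_variable_meta <- function(meta_path) {
  raw <- jsonlite::read_json(meta_path, simplifyVector = FALSE)
  lapply(raw, function(m)
    variable_meta(name = m$name, kind = m$kind,
                  levels = if (!is.null(m$levels)) unlist(m$levels),
                  role = m$role %||% "feature"))
}

#' Write a mixed-type dataset back to CSV (+ optional metadata JSON)
#' @param ds A [mixed_dataset()].
#' @param table_path Output CSV path.
#' @param meta_path Optional output path for the JSON sidecar.
#' @return `ds`, invisibly.
#' @export
write_dataset <- function(ds, table_path, meta_path = NULL) {
  stopifnot(inherits(ds, "mixed_dataset"))
  out <- ds$values
  utils::write.csv(out, table_path, row.names = FALSE, na = "NA")
  if (!is.null(meta_path)) {
    jsonlite::write_json(
      lapply(ds$meta, function(m)
        Filter(Negate(is.null),
               list(name = m$name, kind = m$kind, levels = m$levels,
                    role = m$role))),
      meta_path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(ds)
}

#' Per-row and per-column missingness fractions
#'
#' Missing values in clinical registries are rarely uniform: whole variables
#' or whole records can be largely unobserved.  This profile is the basis for
#' the column-then-row filtering rule of [filter_missing()].
#'
#' @param ds A [mixed_dataset()].
#' @return List with `row` and `column` named fraction vectors and the total
#'   missing-cell `count`.
#' @export
missingness_profile <- function(ds) {
  stopifnot(inherits(ds, "mixed_dataset"))
  m <- ds$missing_mask
  list(row = rowMeans(m), column = colMeans(m), count = sum(m))
}

#' Filter rows and columns by tolerable missingness
#'
#' Applies the greedy two-pass rule: first drop the columns whose missing
#' fraction exceeds `delta_column`, then drop the rows whose missing fraction
#' computed on the remaining columns exceeds `delta_row`.  Both comparisons
#' are strict (`>`).  This is the simple suboptimal alternative to searching
#' for the largest admissible submatrix, and it is idempotent.
#'
#' @param ds A [mixed_dataset()].
#' @param delta_column,delta_row Maximum tolerable missing fractions in
#'   `[0, 1]`.
#' @return The filtered [mixed_dataset()]; the attribute `"filter_report"`
#'   holds kept/dropped row and column ids and the thresholds used.
#' @export
filter_missing <- function(ds, delta_column = 0.3, delta_row = 0.2) {
  stopifnot(inherits(ds, "mixed_dataset"),
            is_fraction(delta_column), is_fraction(delta_row))
  colfrac <- colMeans(ds$missing_mask)
  keep_col <- names(colfrac)[colfrac <= delta_column]
  drop_col <- setdiff(names(colfrac), keep_col)
  if (!length(keep_col))
    stopf("all %d columns exceed delta_column = %g; nothing left to analyse",
          ncol(ds$values), delta_column)
  mask2 <- ds$missing_mask[, keep_col, drop = FALSE]
  rowfrac <- rowMeans(mask2)
  keep_row <- ds$row_ids[rowfrac <= delta_row]
  drop_row <- setdiff(ds$row_ids, keep_row)
  if (!length(keep_row))
    stopf("all rows exceed delta_row = %g on the retained columns", delta_row)
  out <- mixed_dataset(ds$values[keep_row, keep_col, drop = FALSE],
                       ds$meta[keep_col], row_ids = keep_row)
  attr(out, "filter_report") <- list(
    delta_column = delta_column, delta_row = delta_row,
    kept_columns = keep_col, dropped_columns = drop_col,
    kept_rows = keep_row, dropped_rows = drop_row)
  out
}
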