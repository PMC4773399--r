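## HDF5-backed append-only columnar store for analytic output. The heavy
## lifting is in src/hdf5_table.c; this layer owns schema handling, type
## validation, the restricted query language and object backlinks.
##
## Row indices are 0-based and ranges half-open throughout, matching the
## on-disk convention. int64 and *_ref values travel as R doubles (exact
## for IDs below 2^53).

.QUERY_CHUNK <- 65536

#' Define feature-table columns and schemas
#'
#' @param name Column name (unique within the schema).
#' @param kind One of `"int64"`, `"float64"`, `"bool"`, `"string"`,
#'   `"well_ref"`, `"image_ref"`, `"roi_ref"`.
#' @param width Byte width for `"string"` columns (UTF-8, NUL-padded on
#'   disk).
#' @param description Free text.
#' @param columns For `tableSchema()`: [ColumnSpec-class] objects, or one
#'   list of them.
#' @return A [ColumnSpec-class] / [TableSchema-class].
#' @examples
#' sch <- tableSchema(columnSpec("roi", "roi_ref"),
#'                    columnSpec("area", "float64"))
#' @export
columnSpec <- function(name, kind, width = 1L, description = "")
    new("ColumnSpec", name = name, kind = kind, width = as.integer(width),
        description = description)

#' @rdname columnSpec
#' @export
tableSchema <- function(...) {
    columns <- list(...)
    if (length(columns) == 1L && is.list(columns[[1L]]) &&
        !is(columns[[1L]], "ColumnSpec"))
        columns <- columns[[1L]]
    new("TableSchema", columns = columns)
}

.schemaNames <- function(schema) vapply(schema@columns, function(c) c@name, "")
.schemaKinds <- function(schema) vapply(schema@columns, function(c) c@kind, "")
.schemaWidths <- function(schema) vapply(schema@columns, function(c) c@width, 0L)

#' Create or open a feature table
#'
#' `createTable()` writes a new empty table with a frozen schema into an
#' HDF5 file (one group, one chunked dataset per column, schema as group
#' attributes); creating over an existing file is a collision error.
#' `openTable()` reopens a path and recovers the identical schema.
#'
#' @param path HDF5 file path.
#' @param schema A [TableSchema-class].
#' @return A [FeatureTable-class] handle.
#' @examples
#' tab <- createTable(tempfile(fileext = ".h5"),
#'                    tableSchema(columnSpec("v", "float64")))
#' appendRows(tab, list(v = c(1, 2, 3)))
#' rowCount(tab)
#' @export
createTable <- function(path, schema) {
    stopifnot(is(schema, "TableSchema"))
    validObject(schema)
    if (file.exists(path))
        stop("collision error: '", path, "' already exists")
    .Call(C_ht_create, path, .schemaNames(schema), .schemaKinds(schema),
          .schemaWidths(schema))
    new("FeatureTable", path = path, schema = schema)
}

#' @rdname createTable
#' @export
openTable <- function(path) {
    info <- .Call(C_ht_info, path)
    cols <- lapply(seq_along(info$names), function(j)
        columnSpec(info$names[j], info$kinds[j], max(info$widths[j], 1L)))
    new("FeatureTable", path = path, schema = tableSchema(cols))
}

#' Number of rows in a feature table
#'
#' Read from the on-disk row counter, which is advanced only after a
#' complete append — a failed append leaves it unchanged.
#'
#' @param x A [FeatureTable-class].
#' @return Numeric row count.
#' @rdname rowCount
#' @export
setMethod("rowCount", "FeatureTable", function(x) .Call(C_ht_info, x@path)$nrow)

.validateBlock <- function(schema, block) {
    nm <- .schemaNames(schema); kinds <- .schemaKinds(schema)
    widths <- .schemaWidths(schema)
    if (!all(nm %in% names(block)) || !all(names(block) %in% nm))
        stop("shape error: block must cover exactly the schema columns (",
             paste(nm, collapse = ", "), ")")
    block <- block[nm]
    n <- length(block[[1L]])
    out <- vector("list", length(nm))
    for (j in seq_along(nm)) {
        v <- block[[j]]
        if (length(v) != n)
            stop("shape error: ragged block (column '", nm[j], "')")
        k <- kinds[j]
        if (k %in% c("int64", "well_ref", "image_ref", "roi_ref")) {
            if (!is.numeric(v) || anyNA(v) || any(v != floor(v)))
                stop("type error: column '", nm[j], "' (", k,
                     ") needs whole numbers without missing values")
            out[[j]] <- as.double(v)
        } else if (k == "float64") {
            if (!is.numeric(v))
                stop("type error: column '", nm[j], "' needs numeric values")
            v <- as.double(v)
            v[is.na(v)] <- NaN        # NaN is the only missing representation
            out[[j]] <- v
        } else if (k == "bool") {
            if (!is.logical(v) || anyNA(v))
                stop("type error: column '", nm[j],
                     "' needs logical values without missing values")
            out[[j]] <- v
        } else {
            if (!is.character(v) || anyNA(v))
                stop("type error: column '", nm[j],
                     "' needs character values without missing values")
            if (any(nchar(v, type = "bytes") > widths[j]))
                stop("type error: string wider than ", widths[j],
                     " bytes in column '", nm[j], "'")
            out[[j]] <- v
        }
    }
    names(out) <- nm
    out
}

#' Append a row block
#'
#' The block must cover every schema column with equal-length, type-valid
#' vectors. Assigned row indices are contiguous starting at the previous
#' row count; appends are atomic (validation happens before any write, and
#' the visible row count is advanced last).
#'
#' @param table A [FeatureTable-class].
#' @param block Named list of per-column vectors.
#' @return `c(first = <first assigned 0-based index>, n = <rows appended>)`.
#' @rdname appendRows
#' @export
setMethod("appendRows", "FeatureTable", function(table, block) {
    block <- .validateBlock(table@schema, block)
    first <- .Call(C_ht_append, table@path, .schemaKinds(table@schema),
                   .schemaWidths(table@schema), unname(block))
    c(first = first, n = length(block[[1L]]))
})

#' Read a column slice
#'
#' Returns exact previously appended values over the half-open, 0-based
#' row range `[start, stop)`.
#'
#' @param table A [FeatureTable-class].
#' @param columns Column name subset (`NULL` = all, in schema order).
#' @param start,stop Row range; `stop = NULL` means the current row count.
#' @return Named list of per-column vectors.
#' @rdname readRows
#' @export
setMethod("readRows", "FeatureTable",
          function(table, columns = NULL, start = 0, stop = NULL) {
    nm <- .schemaNames(table@schema)
    if (is.null(columns)) columns <- nm
    idx <- match(columns, nm)
    if (anyNA(idx))
        stop("name error: unknown column(s): ",
             paste(columns[is.na(idx)], collapse = ", "))
    nrow <- rowCount(table)
    if (is.null(stop)) stop <- nrow
    if (start < 0 || stop < start || stop > nrow)
        stop("bounds error: need 0 <= start <= stop <= ", nrow)
    .Call(C_ht_read, table@path, nm, .schemaKinds(table@schema),
          .schemaWidths(table@schema), as.integer(idx),
          as.double(start), as.double(stop))
})

#' Restricted row queries
#'
#' The query language is deliberately limited: terms of the form
#' `(column op literal)` with `op` in `==, !=, <, <=, >, >=`, combined
#' with AND only — full SQL-style querying is out of scope by design.
#' `tableCondition()` builds one term; `queryRows()` takes one term or a
#' list of terms and returns the ascending 0-based indices of rows
#' satisfying all of them, evaluating chunk-wise (65,536 rows at a time).
#'
#' @param column Column name.
#' @param op One of `"=="`, `"!="`, `"<"`, `"<="`, `">"`, `">="`.
#' @param value Literal whose type matches the column kind.
#' @param table A [FeatureTable-class].
#' @param condition A condition or list of conditions (AND-combined).
#' @return `tableCondition()`: a condition term. `queryRows()`: numeric
#'   vector of 0-based row indices, ascending.
#' @examples
#' tab <- createTable(tempfile(fileext = ".h5"),
#'                    tableSchema(columnSpec("ch", "int64"),
#'                                columnSpec("v", "float64")))
#' appendRows(tab, list(ch = c(1, 1, 2), v = c(.2, .8, .9)))
#' queryRows(tab, list(tableCondition("v", ">", 0.5),
#'                     tableCondition("ch", "==", 1)))
#' @export
tableCondition <- function(column, op, value) {
    op <- match.arg(op, c("==", "!=", "<", "<=", ">", ">="))
    structure(list(column = column, op = op, value = value),
              class = "tableCondition")
}

.checkCondition <- function(schema, cond) {
    nm <- .schemaNames(schema); kinds <- .schemaKinds(schema)
    j <- match(cond$column, nm)
    if (is.na(j))
        stop("condition error: unknown column '", cond$column, "'")
    k <- kinds[j]
    ok <- if (k %in% c("int64", "float64", "well_ref", "image_ref", "roi_ref"))
        is.numeric(cond$value)
    else if (k == "bool") is.logical(cond$value)
    else is.character(cond$value)
    if (!ok || length(cond$value) != 1L || is.na(cond$value))
        stop("condition error: literal for '", cond$column,
             "' must be a single non-missing ", k, " value")
    invisible(TRUE)
}

#' @rdname tableCondition
#' @export
setMethod("queryRows", "FeatureTable", function(table, condition) {
    if (inherits(condition, "tableCondition")) condition <- list(condition)
    if (!length(condition)) stop("condition error: empty condition")
    for (cond in condition) {
        if (!inherits(cond, "tableCondition"))
            stop("condition error: terms must come from tableCondition()")
        .checkCondition(table@schema, cond)
    }
    cols <- unique(vapply(condition, function(c) c$column, ""))
    n <- rowCount(table)
    hits <- vector("list", ceiling(n / .QUERY_CHUNK) + 1L)
    i <- 0L
    start <- 0
    while (start < n) {
        stop_ <- min(start + .QUERY_CHUNK, n)
        chunk <- readRows(table, cols, start, stop_)
        keep <- rep(TRUE, stop_ - start)
        for (cond in condition) {
            v <- chunk[[cond$column]]
            keep <- keep & switch(cond$op,
                "==" = v == cond$value, "!=" = v != cond$value,
                "<" = v < cond$value, "<=" = v <= cond$value,
                ">" = v > cond$value, ">=" = v >= cond$value)
        }
        keep[is.na(keep)] <- FALSE     # NaN comparisons never match
        i <- i + 1L
        hits[[i]] <- which(keep) - 1 + start
        start <- stop_
    }
    as.double(unlist(hits[seq_len(i)]))
})

#' Rows linked to a source object
#'
#' Feature-table rows carry object references; `backlink()` returns the
#' indices of rows whose reference column equals the target's ID — the
#' inverse lookup (rows to object) is just [readRows()] on the reference
#' column. Equivalent to `queryRows(table, tableCondition(ref_column,
#' "==", target@oid))`.
#'
#' @param table A [FeatureTable-class].
#' @param ref_column Name of a `*_ref` column whose type matches the
#'   target.
#' @param target An [ObjectRef-class].
#' @return Numeric vector of 0-based row indices, ascending.
#' @rdname backlink
#' @export
setMethod("backlink", "FeatureTable", function(table, ref_column, target) {
    stopifnot(is(target, "ObjectRef"))
    nm <- .schemaNames(table@schema)
    j <- match(ref_column, nm)
    if (is.na(j)) stop("name error: unknown column '", ref_column, "'")
    kind <- .schemaKinds(table@schema)[j]
    if (kind != paste0(target@otype, "_ref"))
        stop("type error: column '", ref_column, "' holds ", kind,
             ", not ", target@otype, " references")
    queryRows(table, tableCondition(ref_column, "==", target@oid))
})

#' Export table rows to CSV
#'
#' @param table A [FeatureTable-class].
#' @param path Output CSV path.
#' @param start,stop Half-open 0-based row range (defaults: all rows).
#' @return Number of data rows written, invisibly.
#' @export
exportTableCSV <- function(table, path, start = 0, stop = NULL) {
    vals <- readRows(table, NULL, start, stop)
    df <- as.data.frame(vals, check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
    invisible(nrow(df))
}

#' Canonical feature-table schemas
#'
#' Two layouts are supported for per-cell feature output.
#' `wideFeatureSchema()` gives one row per ROI: reference columns for the
#' well, the image in the well and the ROI, plus one `float64` column per
#' feature x channel (named `feature_<f>_ch_<c>`), e.g. 3 + 25 x 3 = 78
#' columns for 3 channels and 25 features. `longFeatureSchema()` gives one
#' row per (ROI, channel, feature) measurement, with a single value
#' column.
#'
#' @param channels,n_features Layout parameters.
#' @return A [TableSchema-class].
#' @export
wideFeatureSchema <- function(channels, n_features) {
    cols <- list(columnSpec("well", "well_ref", description = "source well"),
                 columnSpec("image", "image_ref", description = "image in the well"),
                 columnSpec("roi", "roi_ref", description = "cell ROI"))
    for (f in seq_len(n_features)) for (ch in seq_len(channels))
        cols[[length(cols) + 1L]] <-
            columnSpec(sprintf("feature_%d_ch_%d", f, ch), "float64")
    tableSchema(cols)
}

#' @rdname wideFeatureSchema
#' @export
longFeatureSchema <- function() {
    tableSchema(columnSpec("well", "well_ref"),
                columnSpec("image", "image_ref"),
                columnSpec("roi", "roi_ref"),
                columnSpec("channel", "int64"),
                columnSpec("feature", "int64"),
                columnSpec("value", "float64"))
}

#' Register a feature table in the store
#'
#' `attachTable()` records a table file as a store object, optionally
#' linked to the object its rows describe; a linked table inherits that
#' object's permissions, an unlinked table is visible to its owner and
#' admins only. `getTable()` is the permission gate for store-level table
#' access: it returns the [FeatureTable-class] handle only if the caller
#' may read the table.
#'
#' @param store An [HCSStore-class].
#' @param path HDF5 table file.
#' @param target Optional [ObjectRef-class] the table is linked to.
#' @param tref Table [ObjectRef-class].
#' @param as Acting principal.
#' @return `attachTable()`: the table [ObjectRef-class]; `getTable()`: a
#'   [FeatureTable-class].
#' @export
attachTable <- function(store, path, target = NULL, as = NULL) {
    if (!is.null(target)) .getObject(store, target)
    .putObject(store, "table",
               list(path = path,
                    linked_to = if (is.null(target)) NULL
                                else list(target@otype, target@oid)),
               as = as)
}

#' @rdname attachTable
#' @export
getTable <- function(store, tref, as = NULL) {
    p <- .resolvePrincipal(store, as)
    if (!.canReadTable(store, p, tref))
        stop("access error: '", p@user_id, "' may not read this table")
    openTable(.getObject(store, tref)$path)
}
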