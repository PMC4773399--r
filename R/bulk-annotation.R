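## Bulk spreadsheet import/export: CSV/TSV sheets keyed by well address (or
## image name) become one map annotation per data row, pairs ordered as the
## sheet columns, with "Header [unit]" units carried into the pair's unit
## field.

.BULK_NS <- "hcstore:/bulk_annotations"

#' Describe how a sheet maps onto the store
#'
#' @param target_level Annotate `"well"`s (key column holds well
#'   addresses) or `"image"`s (key column holds image names).
#' @param key_column Header of the key column.
#' @param unit_syntax Parse headers like `"Temperature [°C]"` into a key
#'   and a unit.
#' @param namespace Namespace applied to created annotations.
#' @param on_unmatched `"error"` or `"skip"` for keys that match nothing.
#' @return A `sheetMapping` list used by [loadSheet()] / [exportSheet()].
#' @export
sheetMapping <- function(target_level = c("well", "image"),
                         key_column = "Well", unit_syntax = TRUE,
                         namespace = .BULK_NS,
                         on_unmatched = c("error", "skip")) {
    list(target_level = match.arg(target_level), key_column = key_column,
         unit_syntax = unit_syntax, namespace = namespace,
         on_unmatched = match.arg(on_unmatched))
}

.sheetDelim <- function(path, delim) {
    if (!is.null(delim)) return(delim)
    if (tolower(tools::file_ext(path)) %in% c("tsv", "txt")) "\t" else ","
}

.splitHeaderUnit <- function(header) {
    m <- regmatches(header, regexec("^(.*?)\\s*\\[(.+)\\]\\s*$", header))[[1L]]
    if (length(m) == 3L) c(key = m[2L], unit = m[3L])
    else c(key = trimws(header), unit = NA_character_)
}

## case-insensitive, zero-padding-tolerant address -> well oid lookup
.plateAddressMap <- function(store, plate) {
    p <- .getObject(store, plate)
    out <- new.env(parent = emptyenv())
    for (r in seq_len(p$rows) - 1L) for (co in seq_len(p$columns) - 1L) {
        oid <- p$wells[r + 1L, co + 1L]
        if (!is.na(oid))
            out[[toupper(wellAddress(r, co))]] <- oid
    }
    out
}

.normAddress <- function(key) {
    m <- regmatches(key, regexec("^([A-Za-z]+)0*([0-9]+)$", trimws(key)))[[1L]]
    if (length(m) != 3L) return(NA_character_)
    paste0(toupper(m[2L]), m[3L])
}

#' Load a spreadsheet as map annotations
#'
#' Reads a CSV/TSV sheet (UTF-8, BOM-tolerant, CRLF or LF, RFC-4180
#' quoting) with a header row, matches each data row to a well of the
#' plate by its address (case-insensitively, tolerating zero padding:
#' `"a01"` matches `"A1"`) — or to an image by name — and attaches one
#' [MapAnnotation-class] per row whose pairs follow the sheet's column
#' order. With `unit_syntax` on, a header `"Temperature [°C]"` yields key
#' `"Temperature"` and unit `"°C"` on every pair in that column.
#'
#' @param store An [HCSStore-class].
#' @param path Sheet file; delimiter by extension (`.csv` comma,
#'   `.tsv`/`.txt` tab) unless `delim` overrides it.
#' @param plate Plate [ObjectRef-class] whose wells/images are targeted.
#' @param mapping A [sheetMapping()].
#' @param delim Optional delimiter override.
#' @param validate_units Check units against the quantities registry.
#' @param as Acting principal.
#' @return Report list: `rows_read`, `annotations_created`, `unmatched`
#'   (character vector of unmatched keys).
#' @examples
#' st <- initStore(tempfile("store"))
#' p <- createPlate(st, "p", format = 384)
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("Well,Cell line,Temperature [°C]",
#'              "A1,U2OS,37", "B1,HeLa,37"), f)
#' loadSheet(st, f, p)$annotations_created   # 2
#' @export
loadSheet <- function(store, path, plate, mapping = sheetMapping(),
                      delim = NULL, validate_units = FALSE, as = NULL) {
    .getObject(store, plate)
    sheet <- tryCatch(
        utils::read.csv(path, sep = .sheetDelim(path, delim),
                        check.names = FALSE, colClasses = "character",
                        fileEncoding = "UTF-8-BOM"),
        error = function(e) stop("parse error: ", conditionMessage(e)))
    headers <- names(sheet)
    ki <- match(mapping$key_column, headers)
    if (is.na(ki))
        stop("mapping error: key column '", mapping$key_column,
             "' not in sheet header")
    value_cols <- setdiff(seq_along(headers), ki)
    hu <- lapply(headers[value_cols], function(h)
        if (mapping$unit_syntax) .splitHeaderUnit(h)
        else c(key = h, unit = NA_character_))
    if (validate_units)
        for (x in hu) if (!is.na(x[["unit"]]))
            .lookupUnit(x[["unit"]], defaultUnitRegistry())

    addr <- if (mapping$target_level == "well") .plateAddressMap(store, plate)
    imgByName <- if (mapping$target_level == "image") {
        e <- new.env(parent = emptyenv())
        walk <- .containedRefs(store, plate)
        for (ref in walk)
            if (ref@otype == "image") {
                o <- .getObject(store, ref)
                e[[o$name]] <- ref@oid
            }
        e
    }

    created <- 0L; unmatched <- character()
    for (i in seq_len(nrow(sheet))) {
        key <- sheet[i, ki]
        target <- if (mapping$target_level == "well") {
            a <- .normAddress(key)
            oid <- if (!is.na(a)) addr[[a]]
            if (is.null(oid) || is.na(a)) NULL else objectRef("well", oid)
        } else {
            oid <- imgByName[[key]]
            if (is.null(oid)) NULL else objectRef("image", oid)
        }
        if (is.null(target)) {
            if (mapping$on_unmatched == "error")
                stop("match error: no ", mapping$target_level, " for key '",
                     key, "' (row ", i, ")")
            unmatched <- c(unmatched, key)
            next
        }
        pairs <- data.frame(
            key = vapply(hu, `[[`, "", "key"),
            value = as.character(unlist(sheet[i, value_cols, drop = TRUE])),
            unit = vapply(hu, `[[`, "", "unit"),
            stringsAsFactors = FALSE)
        ann <- mapAnnotation(pairs, namespace = mapping$namespace,
                             validate_units = FALSE)
        annotate(store, target, ann, as = as)
        created <- created + 1L
    }
    list(rows_read = nrow(sheet), annotations_created = created,
         unmatched = unmatched)
}

#' Export map annotations back to a sheet
#'
#' Writes one data row per map annotation found in `namespace` on the
#' plate's wells (in row-major well order, then link order), with the key
#' column first and one column per pair. Reloading the file under the same
#' mapping recreates value-identical annotations; all annotations in the
#' namespace must therefore share one key/unit sequence.
#'
#' @param store An [HCSStore-class].
#' @param plate Plate [ObjectRef-class].
#' @param namespace Namespace to export.
#' @param path Output file; delimiter by extension as in [loadSheet()].
#' @param mapping A [sheetMapping()] (key column name and level).
#' @param delim Optional delimiter override.
#' @param as Acting principal.
#' @return Number of data rows written.
#' @export
exportSheet <- function(store, plate, namespace, path,
                        mapping = sheetMapping(namespace = namespace),
                        delim = NULL, as = NULL) {
    p <- .getObject(store, plate)
    rows <- list(); header_pairs <- NULL
    for (r in seq_len(p$rows) - 1L) for (co in seq_len(p$columns) - 1L) {
        oid <- p$wells[r + 1L, co + 1L]
        if (is.na(oid)) next
        anns <- getAnnotations(store, objectRef("well", oid),
                               namespace = namespace, as = as)
        for (ann in anns) {
            if (!is(ann, "MapAnnotation")) next
            sig <- paste(ann@pairs$key, ann@pairs$unit, collapse = "\r")
            if (is.null(header_pairs)) header_pairs <- ann@pairs[, c("key", "unit")]
            else if (!identical(paste(header_pairs$key, header_pairs$unit,
                                      collapse = "\r"), sig))
                stop("cannot export: annotations in '", namespace,
                     "' carry differing key/unit sequences")
            rows[[length(rows) + 1L]] <- c(wellAddress(r, co), ann@pairs$value)
        }
    }
    headers <- if (is.null(header_pairs)) character()
    else ifelse(is.na(header_pairs$unit), header_pairs$key,
                sprintf("%s [%s]", header_pairs$key, header_pairs$unit))
    headers <- c(mapping$key_column, headers)
    df <- if (length(rows))
        as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
    else as.data.frame(matrix(character(), 0, length(headers)),
                       stringsAsFactors = FALSE)
    names(df) <- headers
    utils::write.table(df, path, sep = .sheetDelim(path, delim),
                       row.names = FALSE, qmethod = "double",
                       fileEncoding = "UTF-8")
    length(rows)
}
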