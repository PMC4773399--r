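#' @import methods
NULL

.OTYPES <- c("screen", "plate", "well", "field", "image", "channel",
             "reagent", "roi", "annotation", "table")

#' Reference to a stored object
#'
#' An \code{ObjectRef} is the universal handle of the store: a pair of an
#' object-type tag and a stable non-negative integer ID. Every storage
#' strategy in the package (hierarchy records, annotations, feature-table
#' reference columns) links through these handles.
#'
#' @slot otype Object-type tag, one of \code{"screen"}, \code{"plate"},
#'   \code{"well"}, \code{"field"}, \code{"image"}, \code{"channel"},
#'   \code{"reagent"}, \code{"roi"}, \code{"annotation"}, \code{"table"}.
#' @slot oid Non-negative integer ID, unique within its type for the
#'   lifetime of a store (IDs are never reused).
#'
#' @seealso [objectRef()], [HCSStore-class]
#' @export
setClass("ObjectRef", representation(otype = "character", oid = "numeric"),
         validity = function(object) {
             if (length(object@otype) != 1L || !(object@otype %in% .OTYPES))
                 return(sprintf("otype must be one of: %s",
                                paste(.OTYPES, collapse = ", ")))
             if (length(object@oid) != 1L || is.na(object@oid) ||
                 object@oid < 0 || object@oid != floor(object@oid))
                 return("oid must be a single non-negative integer")
             TRUE
         })

#' Construct an ObjectRef
#'
#' @param otype Object-type tag (see [ObjectRef-class]).
#' @param oid Non-negative integer ID.
#' @return An [ObjectRef-class] object.
#' @examples
#' objectRef("plate", 1)
#' @export
objectRef <- function(otype, oid) new("ObjectRef", otype = otype, oid = as.numeric(oid))

setMethod("show", "ObjectRef", function(object) {
    cat(sprintf("<%s:%d>\n", object@otype, as.integer(object@oid)))
})

#' HCS metadata store
#'
#' A single-rooted store for high content screening metadata: the
#' screen/plate/well/field/image containment hierarchy, reagents, ROIs,
#' annotations (map, file, tag), registered feature tables, principals and
#' group policies, and the text-search index. The store lives in memory,
#' backed by an environment (so operations mutate it in place, like a
#' database handle), and persists under a directory on disk via
#' [saveStore()] / [openStore()]. File-annotation payloads are kept
#' content-addressed under \code{<path>/files/}.
#'
#' @slot path Store directory on disk.
#' @slot data Backing environment (internal; use the accessor functions).
#'
#' @seealso [initStore()], [openStore()], [saveStore()]
#' @export
setClass("HCSStore", representation(path = "character", data = "environment"))

setMethod("show", "HCSStore", function(object) {
    counts <- table(vapply(ls(object@data$objects),
                           function(k) sub(":.*$", "", k), ""))
    cat("HCSStore at", object@path, "\n")
    if (length(counts)) {
        for (t in intersect(.OTYPES, names(counts)))
            cat(sprintf("  %-10s %d\n", t, counts[[t]]))
    } else cat("  (empty)\n")
})

#' Unit-bearing scalar quantity
#'
#' @slot value Finite numeric value.
#' @slot unit Unit symbol, resolved against a unit registry.
#' @slot dimension Physical dimension of the unit (\code{"length"},
#'   \code{"time"}, \code{"temperature"}, \code{"electric-potential"},
#'   \code{"pressure"}, \code{"frequency"}, \code{"angle"},
#'   \code{"dimensionless"}, or a registry extension).
#' @seealso [quantity()], [convertQuantity()]
#' @export
setClass("Quantity",
         representation(value = "numeric", unit = "character",
                        dimension = "character"),
         validity = function(object) {
             if (length(object@value) != 1L || !is.finite(object@value))
                 return("value must be a single finite number")
             TRUE
         })

setMethod("show", "Quantity", function(object) {
    cat(sprintf("%g %s (%s)\n", object@value, object@unit, object@dimension))
})

#' Ordered key-value map annotation
#'
#' The flexible experimental-metadata carrier: an ordered list of
#' (key, value, optional unit) pairs under a namespace. Keys may repeat and
#' pair order is preserved exactly as inserted.
#'
#' @slot namespace Namespace string (URI-like, may be empty).
#' @slot pairs \code{data.frame} with character columns \code{key},
#'   \code{value}, \code{unit} (\code{NA} for unitless pairs).
#' @slot owner User ID of the annotation owner (filled in by [annotate()]).
#' @seealso [mapAnnotation()], [annotate()], [queryMap()]
#' @export
setClass("MapAnnotation",
         representation(namespace = "character", pairs = "data.frame",
                        owner = "character"),
         validity = function(object) {
             p <- object@pairs
             if (!all(c("key", "value", "unit") %in% names(p)))
                 return("pairs must have columns key, value, unit")
             if (nrow(p) && any(!nzchar(p$key) | is.na(p$key)))
                 return("keys must be non-empty")
             TRUE
         })

setMethod("show", "MapAnnotation", function(object) {
    cat(sprintf("MapAnnotation [%s] %d pair(s)\n",
                object@namespace, nrow(object@pairs)))
    for (i in seq_len(nrow(object@pairs))) {
        u <- object@pairs$unit[i]
        cat(sprintf("  %s : %s%s\n", object@pairs$key[i], object@pairs$value[i],
                    if (is.na(u)) "" else paste0(" [", u, "]")))
    }
})

#' File annotation (content-addressed attachment)
#'
#' @slot namespace Namespace string.
#' @slot filename Original file name.
#' @slot mimetype MIME type (inferred from the extension when not given).
#' @slot checksum MD5 hex digest of the payload.
#' @slot owner User ID of the annotation owner.
#' @seealso [attachFile()], [annotationPayload()]
#' @export
setClass("FileAnnotation",
         representation(namespace = "character", filename = "character",
                        mimetype = "character", checksum = "character",
                        owner = "character"))

setMethod("show", "FileAnnotation", function(object) {
    cat(sprintf("FileAnnotation [%s] %s (%s, md5 %s)\n", object@namespace,
                object@filename, object@mimetype, object@checksum))
})

#' Tag annotation
#'
#' @slot label Non-empty text label.
#' @seealso [tagAnnotation()], [annotate()]
#' @export
setClass("TagAnnotation", representation(label = "character", owner = "character"),
         validity = function(object) {
             if (length(object@label) != 1L || is.na(object@label) ||
                 !nzchar(object@label))
                 return("label must be non-empty")
             TRUE
         })

setMethod("show", "TagAnnotation", function(object)
    cat(sprintf("TagAnnotation '%s'\n", object@label)))

.COLUMN_KINDS <- c("int64", "float64", "bool", "string",
                   "well_ref", "image_ref", "roi_ref")

#' Typed column specification for a feature table
#'
#' @slot name Column name, unique within its schema.
#' @slot kind One of \code{"int64"}, \code{"float64"}, \code{"bool"},
#'   \code{"string"} (fixed width), \code{"well_ref"}, \code{"image_ref"},
#'   \code{"roi_ref"}.
#' @slot width Byte width for \code{"string"} columns (ignored otherwise).
#' @slot description Free-text description.
#' @seealso [columnSpec()], [tableSchema()]
#' @export
setClass("ColumnSpec",
         representation(name = "character", kind = "character",
                        width = "integer", description = "character"),
         validity = function(object) {
             if (!nzchar(object@name)) return("column name must be non-empty")
             if (!(object@kind %in% .COLUMN_KINDS))
                 return(sprintf("kind must be one of: %s",
                                paste(.COLUMN_KINDS, collapse = ", ")))
             if (object@kind == "string" && object@width < 1L)
                 return("string columns need width >= 1")
             TRUE
         })

#' Feature-table schema
#'
#' An ordered list of typed columns; immutable once a table has been
#' created on disk.
#'
#' @slot columns List of [ColumnSpec-class] objects with unique names.
#' @seealso [tableSchema()], [createTable()]
#' @export
setClass("TableSchema", representation(columns = "list"),
         validity = function(object) {
             if (length(object@columns) < 1L)
                 return("schema needs at least one column")
             nm <- vapply(object@columns, function(c) c@name, "")
             if (anyDuplicated(nm)) return("duplicate column names in schema")
             TRUE
         })

setMethod("show", "TableSchema", function(object) {
    cat(sprintf("TableSchema with %d column(s)\n", length(object@columns)))
    for (c in object@columns)
        cat(sprintf("  %-20s %s%s\n", c@name, c@kind,
                    if (c@kind == "string") sprintf("(%d)", c@width) else ""))
})

#' Handle to an HDF5-backed feature table
#'
#' An append-only columnar row store in a single HDF5 file: one group per
#' table, one chunked extensible dataset per column, schema held as group
#' attributes. Row indices are 0-based and ranges are half-open, matching
#' the on-disk convention.
#'
#' @slot path HDF5 file path.
#' @slot schema The frozen [TableSchema-class].
#' @seealso [createTable()], [openTable()], [appendRows()], [readRows()],
#'   [queryRows()], [backlink()]
#' @export
setClass("FeatureTable", representation(path = "character", schema = "TableSchema"))

setMethod("show", "FeatureTable", function(object) {
    cat(sprintf("FeatureTable '%s': %d column(s), %d row(s)\n", object@path,
                length(object@schema@columns), rowCount(object)))
})

#' Acting principal (user + groups)
#'
#' @slot user_id Non-empty user ID.
#' @slot group_ids Character vector of group memberships.
#' @slot is_admin Whether the principal bypasses permission checks.
#' @seealso [principal()], [canRead()], [canAnnotate()]
#' @export
setClass("Principal",
         representation(user_id = "character", group_ids = "character",
                        is_admin = "logical"),
         validity = function(object) {
             if (length(object@user_id) != 1L || !nzchar(object@user_id))
                 return("user_id must be non-empty")
             TRUE
         })

setMethod("show", "Principal", function(object)
    cat(sprintf("Principal '%s'%s groups: %s\n", object@user_id,
                if (object@is_admin) " (admin)" else "",
                paste(object@group_ids, collapse = ", "))))

#' Per-channel rendering settings for thumbnails
#'
#' @slot window_min,window_max Numeric vectors (one entry per channel)
#'   giving the intensity window; \code{window_min < window_max} is required
#'   for every active channel.
#' @slot color Integer matrix (channels x 3) of RGB tints in 0..255.
#' @slot active Logical vector; inactive channels are skipped.
#' @seealso [renderingSettings()], [renderThumbnail()]
#' @export
setClass("RenderingSettings",
         representation(window_min = "numeric", window_max = "numeric",
                        color = "matrix", active = "logical"),
         validity = function(object) {
             n <- length(object@window_min)
             if (length(object@window_max) != n || length(object@active) != n ||
                 nrow(object@color) != n)
                 return("per-channel fields must have equal length")
             bad <- object@active & !(object@window_min < object@window_max)
             if (any(bad)) return("window_min must be < window_max for active channels")
             TRUE
         })

#' Synthetic-screen configuration
#'
#' Describes a complete synthetic HCS screen: plates, wells, fields,
#' channels, simulated cells (ROIs) and per-cell features. The defaults are
#' a standard full-scale screening run: one 384-well plate, 5 fields per
#' well, 3 channels, 50 cells per image, and 25 features per channel per
#' cell, with standard-normal feature values. The seed is mandatory so
#' every generated screen is reproducible.
#'
#' @slot n_plates Number of plates.
#' @slot plate_format One of 96, 384, 1536.
#' @slot fields_per_well Imaged fields per well.
#' @slot channels Channels per image.
#' @slot cells Cell-count distribution: \code{list(kind = "constant", k = )}
#'   or \code{list(kind = "poisson", lambda = )}.
#' @slot n_features Features per channel per cell.
#' @slot feature_mean,feature_sd Gaussian feature parameters (recycled over
#'   features).
#' @slot seed Integer RNG seed (mandatory).
#' @seealso [screenConfig()], [generateScreen()]
#' @export
setClass("ScreenConfig",
         representation(n_plates = "numeric", plate_format = "numeric",
                        fields_per_well = "numeric", channels = "numeric",
                        cells = "list", n_features = "numeric",
                        feature_mean = "numeric", feature_sd = "numeric",
                        seed = "numeric"),
         validity = function(object) {
             cnt <- c(object@n_plates, object@fields_per_well,
                      object@channels, object@n_features)
             if (any(is.na(cnt)) || any(cnt < 0) || any(cnt != floor(cnt)))
                 return("counts must be non-negative integers")
             if (!(object@plate_format %in% c(96, 384, 1536)))
                 return("plate_format must be 96, 384 or 1536")
             if (length(object@seed) != 1L || is.na(object@seed))
                 return("seed is mandatory")
             if (!(object@cells$kind %in% c("constant", "poisson")))
                 return("cells$kind must be 'constant' or 'poisson'")
             TRUE
         })

setMethod("show", "ScreenConfig", function(object) {
    cells <- if (object@cells$kind == "constant")
        sprintf("%d cells/image", object@cells$k)
    else sprintf("Poisson(%g) cells/image", object@cells$lambda)
    cat(sprintf("ScreenConfig: %d x %d-well plate(s), %d field(s)/well, %d channel(s), %s, %d feature(s)/channel/cell, seed %d\n",
                object@n_plates, object@plate_format, object@fields_per_well,
                object@channels, cells, object@n_features, object@seed))
})
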