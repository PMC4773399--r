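#' @rdname annotate
#' @export
setGeneric("annotate", function(store, target, annotation, as = NULL)
    standardGeneric("annotate"))

#' @rdname rowCount
#' @export
setGeneric("rowCount", function(x) standardGeneric("rowCount"))

#' @rdname appendRows
#' @export
setGeneric("appendRows", function(table, block) standardGeneric("appendRows"))

#' @rdname readRows
#' @export
setGeneric("readRows", function(table, columns = NULL, start = 0, stop = NULL)
    standardGeneric("readRows"))

#' @rdname tableCondition
#' @export
setGeneric("queryRows", function(table, condition) standardGeneric("queryRows"))

#' @rdname backlink
#' @export
setGeneric("backlink", function(table, ref_column, target) standardGeneric("backlink"))

#' @rdname canRead
#' @export
setGeneric("canRead", function(store, principal, ref) standardGeneric("canRead"))

#' @rdname canRead
#' @export
setGeneric("canAnnotate", function(store, principal, ref) standardGeneric("canAnnotate"))
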