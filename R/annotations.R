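## Flexible metadata attachments. Annotations are first-class objects
## (otype "annotation") linked many-to-many onto targets; map-annotation
## pairs are an ordered multimap (duplicate keys allowed, order preserved),
## file-annotation payloads live content-addressed under <store>/files/.

#' Construct annotations
#'
#' `mapAnnotation()` builds an ordered key-value map; pass pairs as a
#' `data.frame` with columns `key`, `value` and optionally `unit`, or as a
#' named character vector. Duplicate keys are allowed and insertion order
#' is preserved. Units, when present, are validated against the quantities
#' registry unless `validate_units = FALSE`.
#'
#' @param pairs `data.frame(key, value, unit)` or named character vector.
#' @param namespace Namespace string (may be empty).
#' @param validate_units Check unit symbols against `registry`.
#' @param registry Unit registry (see [defaultUnitRegistry()]).
#' @param label Tag text for `tagAnnotation()`.
#' @return A [MapAnnotation-class] or [TagAnnotation-class].
#' @examples
#' mapAnnotation(data.frame(key = "Temperature", value = "37", unit = "°C"))
#' mapAnnotation(c("Cell line" = "U2OS"))
#' @export
mapAnnotation <- function(pairs, namespace = "", validate_units = TRUE,
                          registry = defaultUnitRegistry()) {
    if (is.character(pairs))
        pairs <- data.frame(key = names(pairs), value = unname(pairs),
                            unit = NA_character_, stringsAsFactors = FALSE)
    if (is.null(pairs$unit)) pairs$unit <- NA_character_
    pairs <- data.frame(key = as.character(pairs$key),
                        value = as.character(pairs$value),
                        unit = as.character(pairs$unit),
                        stringsAsFactors = FALSE)
    if (validate_units)
        for (u in pairs$unit[!is.na(pairs$unit)]) .lookupUnit(u, registry)
    new("MapAnnotation", namespace = namespace, pairs = pairs, owner = "")
}

#' @rdname mapAnnotation
#' @export
tagAnnotation <- function(label) new("TagAnnotation", label = label, owner = "")

.annRecord <- function(ann) {
    if (is(ann, "MapAnnotation"))
        list(ann_kind = "map", namespace = ann@namespace, pairs = ann@pairs)
    else if (is(ann, "TagAnnotation"))
        list(ann_kind = "tag", namespace = "", label = ann@label)
    else stop("unsupported annotation class: ", class(ann))
}

.annFromRecord <- function(rec) {
    switch(rec$ann_kind,
        map = new("MapAnnotation", namespace = rec$namespace,
                  pairs = rec$pairs, owner = rec$owner),
        tag = new("TagAnnotation", label = rec$label, owner = rec$owner),
        file = new("FileAnnotation", namespace = rec$namespace,
                   filename = rec$filename, mimetype = rec$mimetype,
                   checksum = rec$checksum, owner = rec$owner))
}

.addLink <- function(store, annRef, target, creator) {
    k <- .key(target@otype, target@oid)
    idx <- store@data$linksByTarget[[k]]
    if (!is.null(idx))
        for (i in idx) {
            l <- store@data$links[[i]]
            if (!is.null(l) && l$ann == annRef@oid)
                stop("duplicate annotation link")
        }
    store@data$links[[length(store@data$links) + 1L]] <-
        list(ann = annRef@oid, ttype = target@otype, tid = target@oid,
             creator = creator)
    store@data$linksByTarget[[k]] <- c(idx, length(store@data$links))
    invisible(annRef)
}

#' Attach an annotation to an object
#'
#' Stores the annotation (if new) and links it to the target. The caller
#' must hold annotate permission on the target. Annotations are shared
#' objects: the same annotation ref may be linked to many targets, but a
#' given (annotation, target) pair only once.
#'
#' @param store An [HCSStore-class].
#' @param target [ObjectRef-class] of any non-annotation object.
#' @param annotation A [MapAnnotation-class], [TagAnnotation-class], or an
#'   existing annotation [ObjectRef-class] to link again.
#' @param as Acting principal.
#' @return [ObjectRef-class] of the annotation.
#' @examples
#' st <- initStore(tempfile("store"))
#' p <- createPlate(st, "p", format = 96)
#' w <- wellAt(st, p, "A1")
#' annotate(st, w, mapAnnotation(c("Cell line" = "U2OS")))
#' length(getAnnotations(st, w))
#' @rdname annotate
#' @export
setMethod("annotate", signature("HCSStore", "ObjectRef", "ANY"),
          function(store, target, annotation, as = NULL) {
    if (target@otype == "annotation")
        stop("annotations cannot target other annotations")
    .getObject(store, target)
    p <- .resolvePrincipal(store, as)
    if (!canAnnotate(store, p, target))
        stop("access error: '", p@user_id, "' may not annotate <",
             .key(target@otype, target@oid), ">")
    if (is(annotation, "ObjectRef")) {
        stopifnot(annotation@otype == "annotation")
        .getObject(store, annotation)
        return(.addLink(store, annotation, target, p@user_id))
    }
    rec <- .annRecord(annotation)
    ref <- .putObject(store, "annotation", rec, as = p)
    .addLink(store, ref, target, p@user_id)
})

#' Retrieve annotations linked to an object
#'
#' Returns the annotations linked to `target` in link-creation order,
#' optionally restricted to an exact namespace match. The caller must be
#' able to read the target; individual annotations the caller cannot read
#' are filtered out.
#'
#' @param store An [HCSStore-class].
#' @param target [ObjectRef-class].
#' @param namespace Optional exact-match namespace filter.
#' @param as Acting principal.
#' @return List of annotation objects ([MapAnnotation-class],
#'   [FileAnnotation-class], [TagAnnotation-class]), with the annotation
#'   [ObjectRef-class] in attribute `"ref"`.
#' @export
getAnnotations <- function(store, target, namespace = NULL, as = NULL) {
    .getObject(store, target)
    p <- .resolvePrincipal(store, as)
    if (!canRead(store, p, target))
        stop("access error: '", p@user_id, "' may not read <",
             .key(target@otype, target@oid), ">")
    idx <- store@data$linksByTarget[[.key(target@otype, target@oid)]]
    out <- list()
    for (i in idx) {
        l <- store@data$links[[i]]
        if (is.null(l)) next
        aref <- objectRef("annotation", l$ann)
        if (!canRead(store, p, aref)) next
        rec <- .getObject(store, aref)
        if (!is.null(namespace) && !identical(rec$namespace, namespace)) next
        ann <- .annFromRecord(rec)
        attr(ann, "ref") <- aref
        out[[length(out) + 1L]] <- ann
    }
    out
}

#' Query map annotations by key (and value)
#'
#' Exact, case-sensitive matching over every stored map-annotation pair;
#' fuzzy text search is the job of the search index instead. Results are
#' restricted to targets the caller can read and ordered deterministically
#' by target type then ID.
#'
#' @param store An [HCSStore-class].
#' @param key Pair key (exact match).
#' @param value Optional pair value (exact match); when `NULL`, key-only.
#' @param as Acting principal.
#' @return `data.frame(target_otype, target_oid, annotation_oid)`, one row
#'   per matching link.
#' @export
queryMap <- function(store, key, value = NULL, as = NULL) {
    p <- .resolvePrincipal(store, as)
    hits <- list()
    for (l in store@data$links) {
        if (is.null(l)) next
        rec <- .getObject(store, objectRef("annotation", l$ann))
        if (rec$ann_kind != "map") next
        ok <- rec$pairs$key == key
        if (!is.null(value)) ok <- ok & rec$pairs$value == value
        if (!any(ok)) next
        tref <- objectRef(l$ttype, l$tid)
        if (!canRead(store, p, tref) ||
            !canRead(store, p, objectRef("annotation", l$ann))) next
        hits[[length(hits) + 1L]] <-
            data.frame(target_otype = l$ttype, target_oid = l$tid,
                       annotation_oid = l$ann, stringsAsFactors = FALSE)
    }
    if (!length(hits))
        return(data.frame(target_otype = character(), target_oid = numeric(),
                          annotation_oid = numeric(), stringsAsFactors = FALSE))
    out <- unique(do.call(rbind, hits))
    ord <- order(match(out$target_otype, .OTYPES), out$target_oid,
                 out$annotation_oid)
    out <- out[ord, , drop = FALSE]
    rownames(out) <- NULL
    out
}

.MIME_BY_EXT <- c(txt = "text/plain", csv = "text/csv",
                  tsv = "text/tab-separated-values", m = "text/x-matlab",
                  md = "text/markdown", json = "application/json",
                  pdf = "application/pdf", xls = "application/vnd.ms-excel",
                  doc = "application/msword", png = "image/png",
                  tif = "image/tiff", tiff = "image/tiff",
                  h5 = "application/x-hdf5", yml = "text/yaml",
                  yaml = "text/yaml")

.inferMime <- function(filename) {
    ext <- tolower(tools::file_ext(filename))
    m <- .MIME_BY_EXT[ext]
    if (is.na(m)) "application/octet-stream" else unname(m)
}

#' Attach a file to an object
#'
#' Copies the payload into the store's content-addressed managed area
#' (`<store>/files/<md5>`), records its checksum and MIME type, and links
#' a [FileAnnotation-class] to the target. Attaching the same content
#' twice yields distinct annotation refs with equal checksums.
#'
#' @param store An [HCSStore-class].
#' @param target [ObjectRef-class].
#' @param path Readable file to attach.
#' @param namespace Namespace string.
#' @param mimetype Optional; inferred from the extension when omitted
#'   (fallback `"application/octet-stream"`).
#' @param as Acting principal.
#' @return [ObjectRef-class] of the annotation.
#' @export
attachFile <- function(store, target, path, namespace = "", mimetype = NULL,
                       as = NULL) {
    if (!file.exists(path)) stop("I/O error: cannot read '", path, "'")
    .getObject(store, target)
    p <- .resolvePrincipal(store, as)
    if (!canAnnotate(store, p, target))
        stop("access error: '", p@user_id, "' may not annotate <",
             .key(target@otype, target@oid), ">")
    checksum <- unname(tools::md5sum(path))
    dest <- file.path(store@path, "files", checksum)
    if (!file.exists(dest)) file.copy(path, dest)
    rec <- list(ann_kind = "file", namespace = namespace,
                filename = basename(path),
                mimetype = if (is.null(mimetype)) .inferMime(path) else mimetype,
                checksum = checksum)
    ref <- .putObject(store, "annotation", rec, as = p)
    .addLink(store, ref, target, p@user_id)
    ref
}

#' Read back a file-annotation payload
#'
#' `annotationPayload()` returns the stored bytes; `exportFileAnnotation()`
#' writes them to `dir` under the original filename.
#'
#' @param store An [HCSStore-class].
#' @param ref Annotation [ObjectRef-class] of a file annotation.
#' @param dir Output directory for `exportFileAnnotation()`.
#' @param as Acting principal.
#' @return Raw vector of payload bytes, or (invisibly) the exported path.
#' @export
annotationPayload <- function(store, ref, as = NULL) {
    p <- .resolvePrincipal(store, as)
    if (!canRead(store, p, ref))
        stop("access error: '", p@user_id, "' may not read this annotation")
    rec <- .getObject(store, ref)
    if (rec$ann_kind != "file") stop("not a file annotation")
    f <- file.path(store@path, "files", rec$checksum)
    readBin(f, "raw", file.size(f))
}

#' @rdname annotationPayload
#' @export
exportFileAnnotation <- function(store, ref, dir, as = NULL) {
    rec <- .getObject(store, ref)
    payload <- annotationPayload(store, ref, as = as)
    out <- file.path(dir, rec$filename)
    writeBin(payload, out)
    invisible(out)
}
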