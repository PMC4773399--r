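## Token-based text search. Documents are the store's non-annotation
## objects; each document carries the object's own text (name, reagent
## identifier, ...) plus the text of its linked annotations: tag labels,
## map keys and values, file-annotation filenames and — for text MIME
## types — full payload contents. Tokenization is deliberately simple:
## split on non-alphanumeric characters, lowercase, no stemming, no stop
## words.

.tokenize <- function(text) {
    toks <- unlist(strsplit(tolower(text), "[^a-z0-9]+"))
    toks[nzchar(toks)]
}

.isTextMime <- function(mimetype, filename) {
    startsWith(mimetype, "text/") ||
        tolower(tools::file_ext(filename)) %in% c("csv", "tsv", "m")
}

.objectText <- function(rec) {
    c(if (!is.null(rec$name)) rec$name,
      if (!is.null(rec$identifier)) rec$identifier,
      if (!is.null(rec$description)) rec$description)
}

#' Rebuild the text-search index
#'
#' Full rebuild over every object in the store (incremental indexing is
#' not attempted at this scale). Reindexing twice gives identical search
#' results. Binary file-annotation payloads are skipped and counted.
#'
#' @param store An [HCSStore-class].
#' @return List with `documents` (number indexed) and `binary_skipped`.
#' @export
reindex <- function(store) {
    docs <- list(); skipped <- 0L
    ## gather annotation text per target first
    annText <- new.env(parent = emptyenv())
    for (l in store@data$links) {
        if (is.null(l)) next
        rec <- .getObject(store, objectRef("annotation", l$ann))
        txt <- switch(rec$ann_kind,
            tag = rec$label,
            map = c(rec$pairs$key, rec$pairs$value),
            file = {
                extra <- rec$filename
                if (.isTextMime(rec$mimetype, rec$filename)) {
                    f <- file.path(store@path, "files", rec$checksum)
                    extra <- c(extra, readChar(f, file.size(f),
                                               useBytes = TRUE))
                } else skipped <- skipped + 1L
                extra
            })
        k <- .key(l$ttype, l$tid)
        annText[[k]] <- c(annText[[k]], txt)
    }
    for (k in ls(store@data$objects)) {
        rec <- get(k, envir = store@data$objects, inherits = FALSE)
        if (rec$otype == "annotation") next
        toks <- .tokenize(c(.objectText(rec), annText[[k]]))
        docs[[k]] <- table(toks)
    }
    store@data$index <- list(docs = docs, binary_skipped = skipped)
    list(documents = length(docs), binary_skipped = skipped)
}

#' Search the store
#'
#' Returns the objects whose document contains every query token
#' (case-insensitive AND), ranked by total query-token frequency with ties
#' broken by object type then ID. Results are filtered by the caller's
#' read permission, so a private object never appears for a non-member.
#'
#' @param store An [HCSStore-class] (reindex first).
#' @param query Non-empty free-text query.
#' @param as Acting principal.
#' @return `data.frame(otype, oid, score)` in rank order.
#' @export
searchStore <- function(store, query, as = NULL) {
    toks <- .tokenize(query)
    if (!length(toks)) stop("query error: empty query")
    if (is.null(store@data$index)) stop("index not built; run reindex()")
    p <- .resolvePrincipal(store, as)
    docs <- store@data$index$docs
    hits <- list()
    for (k in names(docs)) {
        freq <- docs[[k]]
        f <- freq[toks]
        if (anyNA(f)) next                      # AND semantics
        parts <- strsplit(k, ":", fixed = TRUE)[[1L]]
        ref <- objectRef(parts[1L], as.numeric(parts[2L]))
        if (!.existsObject(store, ref) || !canRead(store, p, ref)) next
        hits[[length(hits) + 1L]] <-
            data.frame(otype = parts[1L], oid = as.numeric(parts[2L]),
                       score = sum(f), stringsAsFactors = FALSE)
    }
    if (!length(hits))
        return(data.frame(otype = character(), oid = numeric(),
                          score = numeric(), stringsAsFactors = FALSE))
    out <- do.call(rbind, hits)
    out <- out[order(-out$score, match(out$otype, .OTYPES), out$oid), ,
               drop = FALSE]
    rownames(out) <- NULL
    out
}
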