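## Environment-backed object store with directory persistence.
##
## Objects are plain lists held in data$objects keyed "otype:oid". IDs come
## from per-type monotonic counters and are never reused, so a deleted
## object's key simply disappears and any later dereference fails loudly.

.key <- function(otype, oid) sprintf("%s:%d", otype, as.integer(oid))

.storeEnv <- function(path) {
    data <- new.env(parent = emptyenv())
    data$objects <- new.env(parent = emptyenv())
    data$counters <- setNames(numeric(length(.OTYPES)), .OTYPES)
    data$links <- list()              # annotation links, creation order
    data$linksByTarget <- new.env(parent = emptyenv())
    data$principals <- list(root = new("Principal", user_id = "root",
                                       group_ids = "default", is_admin = TRUE))
    data$policies <- c(default = "private")
    data$default_user <- "root"
    data$index <- NULL
    new("HCSStore", path = path, data = data)
}

#' Create, open and save a metadata store
#'
#' `initStore()` creates a new store directory (with a `files/` payload
#' area) and returns an empty in-memory store. `saveStore()` serialises the
#' store state to `<path>/store.rds`; `openStore()` loads it back. The
#' store always starts with an administrative principal `"root"` and a
#' group `"default"` with a `private` policy.
#'
#' @param path Store directory.
#' @param store An [HCSStore-class].
#' @return `initStore()` and `openStore()` return an [HCSStore-class];
#'   `saveStore()` returns the store invisibly.
#' @examples
#' st <- initStore(tempfile("store"))
#' plate <- createPlate(st, "plate-1", format = 96)
#' saveStore(st)
#' st2 <- openStore(st@path)
#' countDescendants(st2, plate, "well")
#' @export
initStore <- function(path) {
    if (file.exists(file.path(path, "store.rds")))
        stop("store already exists at ", path)
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(path, "files"), showWarnings = FALSE)
    store <- .storeEnv(path)
    saveStore(store)
    store
}

#' @rdname initStore
#' @export
openStore <- function(path) {
    f <- file.path(path, "store.rds")
    if (!file.exists(f)) stop("no store at ", path)
    state <- readRDS(f)
    store <- .storeEnv(path)
    list2env(state$objects, envir = store@data$objects)
    store@data$counters <- state$counters
    store@data$links <- state$links
    list2env(state$linksByTarget, envir = store@data$linksByTarget)
    store@data$principals <- state$principals
    store@data$policies <- state$policies
    store@data$default_user <- state$default_user
    store@data$index <- state$index
    store
}

#' @rdname initStore
#' @export
saveStore <- function(store) {
    state <- list(objects = as.list(store@data$objects),
                  counters = store@data$counters,
                  links = store@data$links,
                  linksByTarget = as.list(store@data$linksByTarget),
                  principals = store@data$principals,
                  policies = store@data$policies,
                  default_user = store@data$default_user,
                  index = store@data$index)
    saveRDS(state, file.path(store@path, "store.rds"))
    invisible(store)
}

.newOid <- function(store, otype) {
    oid <- store@data$counters[[otype]] + 1
    store@data$counters[[otype]] <- oid
    oid
}

## allocate n consecutive IDs at once (bulk generation path)
.newOids <- function(store, otype, n) {
    last <- store@data$counters[[otype]]
    store@data$counters[[otype]] <- last + n
    seq_len(n) + last
}

.putObject <- function(store, otype, rec, as = NULL) {
    p <- .resolvePrincipal(store, as)
    oid <- .newOid(store, otype)
    rec$otype <- otype; rec$oid <- oid
    rec$owner <- p@user_id
    rec$group <- if (length(p@group_ids)) p@group_ids[[1L]] else "default"
    assign(.key(otype, oid), rec, envir = store@data$objects)
    objectRef(otype, oid)
}

.getObject <- function(store, ref) {
    stopifnot(is(ref, "ObjectRef"))
    k <- .key(ref@otype, ref@oid)
    if (!exists(k, envir = store@data$objects, inherits = FALSE))
        stop("reference error: no such object <", k, ">")
    get(k, envir = store@data$objects, inherits = FALSE)
}

.setObject <- function(store, ref, rec)
    assign(.key(ref@otype, ref@oid), rec, envir = store@data$objects)

.existsObject <- function(store, ref)
    exists(.key(ref@otype, ref@oid), envir = store@data$objects, inherits = FALSE)

.resolvePrincipal <- function(store, as) {
    if (is.null(as)) as <- store@data$default_user
    if (is(as, "Principal")) return(as)
    p <- store@data$principals[[as]]
    if (is.null(p)) stop("unknown principal '", as, "'")
    p
}

#' Define principals and group policies
#'
#' `addPrincipal()` registers a user with group memberships;
#' `setGroupPolicy()` sets a group's permission level. Levels form the
#' ladder `private < group_read < group_read_annotate`, plus `public_read`
#' which opens reading to everyone. Lowering a group's level after objects
#' exist in that group is refused (data already visible to the group would
#' silently escape the owner's intent otherwise).
#'
#' @param store An [HCSStore-class].
#' @param user_id,group_ids,is_admin Principal fields (see
#'   [Principal-class]).
#' @param group Group ID.
#' @param level One of `"private"`, `"group_read"`, `"group_read_annotate"`,
#'   `"public_read"`.
#' @return The new [Principal-class], or the store invisibly for
#'   `setGroupPolicy()`.
#' @export
addPrincipal <- function(store, user_id, group_ids = "default", is_admin = FALSE) {
    p <- new("Principal", user_id = user_id, group_ids = group_ids,
             is_admin = is_admin)
    store@data$principals[[user_id]] <- p
    for (g in group_ids)
        if (!(g %in% names(store@data$policies)))
            store@data$policies[[g]] <- "private"
    p
}

.LEVELS <- c(private = 1L, group_read = 2L, group_read_annotate = 3L,
             public_read = 4L)

#' @rdname addPrincipal
#' @export
setGroupPolicy <- function(store, group, level) {
    level <- match.arg(level, names(.LEVELS))
    cur <- store@data$policies[group]
    if (!is.na(cur) && .LEVELS[[level]] < .LEVELS[[cur]]) {
        grps <- vapply(as.list(store@data$objects), function(o) o$group, "")
        if (any(grps == group))
            stop("cannot lower policy of group '", group,
                 "': objects exist in it")
    }
    store@data$policies[[group]] <- level
    invisible(store)
}

#' @rdname addPrincipal
#' @export
principal <- function(user_id, group_ids = character(), is_admin = FALSE)
    new("Principal", user_id = user_id, group_ids = group_ids, is_admin = is_admin)

#' Delete an object from the store
#'
#' Deletion is restricted: an object that other objects or annotation
#' links still point at cannot be deleted unless `cascade = TRUE`, in
#' which case the object, its contained descendants and its annotation
#' links are all removed. IDs of deleted objects are never reused.
#'
#' @param store An [HCSStore-class].
#' @param ref [ObjectRef-class] to delete.
#' @param cascade Also delete contained descendants and links.
#' @return Invisibly, the number of objects removed.
#' @export
deleteObject <- function(store, ref, cascade = FALSE) {
    .getObject(store, ref)  # reference error if unknown
    inbound <- .inboundCount(store, ref)
    if (inbound > 0L && !cascade)
        stop("object <", .key(ref@otype, ref@oid), "> has ", inbound,
             " inbound link(s); use cascade = TRUE")
    victims <- if (cascade) .containedRefs(store, ref) else list()
    victims <- c(victims, list(ref))
    n <- 0L
    for (v in victims) {
        k <- .key(v@otype, v@oid)
        if (exists(k, envir = store@data$objects, inherits = FALSE)) {
            rm(list = k, envir = store@data$objects)
            n <- n + 1L
        }
        ## drop annotation links touching the victim
        keep <- vapply(store@data$links, function(l) {
            !is.null(l) && !(l$ttype == v@otype && l$tid == v@oid) &&
                !(v@otype == "annotation" && l$ann == v@oid)
        }, NA)
        if (!all(keep) && length(keep)) {
            store@data$links[!keep] <- list(NULL)
            if (exists(k, envir = store@data$linksByTarget, inherits = FALSE))
                rm(list = k, envir = store@data$linksByTarget)
        }
    }
    invisible(n)
}

## number of references held by OTHER objects / links pointing at ref
.inboundCount <- function(store, ref) {
    n <- 0L
    tt <- ref@otype; ti <- ref@oid
    for (o in as.list(store@data$objects)) {
        if (o$otype == tt && o$oid == ti) next
        n <- n + switch(tt,
            plate = sum(o$otype == "screen" && ti %in% o$plate_refs),
            well = sum(o$otype == "plate" && ti %in% o$wells),
            field = sum(o$otype == "well" && ti %in% o$fields),
            image = sum(o$otype == "field" && identical(o$image, ti)) +
                    sum(o$otype == "roi" && identical(o$image, ti)),
            channel = sum(o$otype == "image" && ti %in% o$channels),
            reagent = sum(o$otype == "well" && identical(o$reagent, ti)) +
                      sum(o$otype == "screen" && ti %in% o$reagent_refs),
            0L)
    }
    for (l in store@data$links)
        if (!is.null(l) && ((l$ttype == tt && l$tid == ti) ||
                            (tt == "annotation" && l$ann == ti)))
            n <- n + 1L
    n
}

## refs contained (strictly below) a container, for cascade deletion
.containedRefs <- function(store, ref) {
    out <- list()
    push <- function(otype, oids)
        for (oid in oids) out[[length(out) + 1L]] <<- objectRef(otype, oid)
    walk <- function(ref) {
        if (!.existsObject(store, ref)) return()
        o <- .getObject(store, ref)
        switch(o$otype,
            screen = { push("plate", o$plate_refs)
                       for (p in o$plate_refs) walk(objectRef("plate", p)) },
            plate = { w <- o$wells[!is.na(o$wells)]; push("well", w)
                      for (x in w) walk(objectRef("well", x)) },
            well = { push("field", o$fields)
                     for (f in o$fields) walk(objectRef("field", f)) },
            field = { push("image", o$image); walk(objectRef("image", o$image)) },
            image = { push("channel", o$channels); push("roi", o$rois) },
            NULL)
    }
    walk(ref)
    out
}
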