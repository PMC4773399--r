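## Group-based permissions. Every object carries one (owner, group)
## ownership record; each group has one policy level on the ladder
## private < group_read < group_read_annotate, plus public_read which opens
## reading to everyone. There are no per-object ACLs.

#' Permission predicates
#'
#' `canRead()` is true iff the principal is an admin, the owner, a group
#' member under a policy of at least `group_read`, or the policy is
#' `public_read`. `canAnnotate()` is true iff admin, owner, or a group
#' member under `group_read_annotate`. Every read path of the package
#' (annotation retrieval, map queries, store-level table reads, search)
#' consults `canRead()`.
#'
#' @param store An [HCSStore-class].
#' @param principal A [Principal-class] (or user ID known to the store).
#' @param ref [ObjectRef-class] of an existing object.
#' @return Logical scalar.
#' @examples
#' st <- initStore(tempfile("store"))
#' addPrincipal(st, "alice", "lab")
#' addPrincipal(st, "bob", "lab")
#' setGroupPolicy(st, "lab", "group_read")
#' p <- createPlate(st, "p", format = 96, as = "alice")
#' canRead(st, principal("bob", "lab"), p)      # TRUE
#' canAnnotate(st, principal("bob", "lab"), p)  # FALSE
#' @aliases canAnnotate
#' @rdname canRead
#' @export
setMethod("canRead", signature("HCSStore", "ANY", "ObjectRef"),
          function(store, principal, ref) {
    p <- .resolvePrincipal(store, principal)
    o <- .getObject(store, ref)
    if (p@is_admin || identical(o$owner, p@user_id)) return(TRUE)
    level <- store@data$policies[o$group]
    if (is.na(level)) level <- "private"
    if (level == "public_read") return(TRUE)
    (o$group %in% p@group_ids) && .LEVELS[[level]] >= .LEVELS[["group_read"]]
})

#' @rdname canRead
#' @export
setMethod("canAnnotate", signature("HCSStore", "ANY", "ObjectRef"),
          function(store, principal, ref) {
    p <- .resolvePrincipal(store, principal)
    o <- .getObject(store, ref)
    if (p@is_admin || identical(o$owner, p@user_id)) return(TRUE)
    level <- store@data$policies[o$group]
    if (is.na(level)) level <- "private"
    (o$group %in% p@group_ids) && level == "group_read_annotate"
})

#' Reassign ownership of an object
#'
#' Supports the facility workflow where data acquired by one user is
#' handed to another for analysis: only the current owner or an admin may
#' reassign. Annotations linked to the object keep their own creators.
#'
#' @param store An [HCSStore-class].
#' @param ref [ObjectRef-class] to reassign.
#' @param new_owner User ID of the new owner.
#' @param actor Acting principal (admin or current owner).
#' @return The updated ownership record `c(owner=, group=)`, invisibly.
#' @export
reassignOwner <- function(store, ref, new_owner, actor = NULL) {
    p <- .resolvePrincipal(store, actor)
    o <- .getObject(store, ref)
    if (!p@is_admin && !identical(o$owner, p@user_id))
        stop("access error: '", p@user_id, "' may not reassign <",
             .key(ref@otype, ref@oid), ">")
    if (is.null(store@data$principals[[new_owner]]))
        stop("unknown principal '", new_owner, "'")
    o$owner <- new_owner
    .setObject(store, ref, o)
    invisible(c(owner = o$owner, group = o$group))
}

## effective readability of a registered feature table: inherit from the
## linked object; an unlinked table is visible to its owner/admin only
.canReadTable <- function(store, principal, tref) {
    p <- .resolvePrincipal(store, principal)
    o <- .getObject(store, tref)
    if (p@is_admin || identical(o$owner, p@user_id)) return(TRUE)
    if (is.null(o$linked_to)) return(FALSE)
    canRead(store, p, objectRef(o$linked_to[[1L]], o$linked_to[[2L]]))
}
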