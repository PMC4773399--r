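## The HCS containment hierarchy: Screen -> Plate -> Well -> Field -> Image
## -> Channel, plus Reagents and ROIs. Pixel data are referenced in place:
## an image's pixel_source is a verbatim path, never copied into the store.

.PLATE_GRIDS <- list(`96` = c(8L, 12L), `384` = c(16L, 24L), `1536` = c(32L, 48L))

#' Create a screen
#'
#' A screen is a collection of plates composing one experiment, with
#' associated reagents.
#'
#' @param store An [HCSStore-class].
#' @param name,description Screen metadata.
#' @param as Acting principal (user ID or [Principal-class]); defaults to
#'   the store's default user.
#' @return [ObjectRef-class] of the new screen.
#' @export
createScreen <- function(store, name, description = "", as = NULL)
    .putObject(store, "screen",
               list(name = name, description = description,
                    plate_refs = numeric(), reagent_refs = numeric()), as = as)

#' @rdname createScreen
#' @param screen,plate Screen and plate refs to link.
#' @export
addPlateToScreen <- function(store, screen, plate) {
    s <- .getObject(store, screen); .getObject(store, plate)
    if (plate@oid %in% s$plate_refs)
        stop("plate already linked to this screen")
    s$plate_refs <- c(s$plate_refs, plate@oid)
    .setObject(store, screen, s)
    invisible(screen)
}

#' Create a multiwell plate with all wells
#'
#' Standard formats map to the SBS grid conventions 96 = 8x12,
#' 384 = 16x24, 1536 = 32x48; every well of the grid is instantiated.
#' Non-standard geometries are available through `rows`/`columns`.
#'
#' @param store An [HCSStore-class].
#' @param name Plate name.
#' @param format One of 96, 384, 1536 (ignored when `rows` is given).
#' @param rows,columns Advanced: explicit grid geometry.
#' @param as Acting principal.
#' @return [ObjectRef-class] of the new plate.
#' @examples
#' st <- initStore(tempfile("store"))
#' p <- createPlate(st, "assay-plate", format = 384)
#' countDescendants(st, p, "well")   # 384
#' @export
createPlate <- function(store, name, format = 96, rows = NULL, columns = NULL,
                        as = NULL) {
    if (is.null(rows)) {
        g <- .PLATE_GRIDS[[as.character(format)]]
        if (is.null(g))
            stop("format error: unsupported plate format '", format,
                 "' (use 96, 384 or 1536, or give rows/columns)")
        rows <- g[1L]; columns <- g[2L]
    }
    stopifnot(rows >= 1, columns >= 1)
    ref <- .putObject(store, "plate",
                      list(name = name, rows = as.integer(rows),
                           columns = as.integer(columns),
                           wells = matrix(NA_real_, rows, columns)), as = as)
    ## instantiate the full grid with bulk ID allocation
    n <- rows * columns
    oids <- .newOids(store, "well", n)
    p <- .resolvePrincipal(store, as)
    grp <- if (length(p@group_ids)) p@group_ids[[1L]] else "default"
    idx <- 0L
    recs <- vector("list", n); keys <- character(n)
    for (r in seq_len(rows) - 1L) for (co in seq_len(columns) - 1L) {
        idx <- idx + 1L
        recs[[idx]] <- list(otype = "well", oid = oids[idx],
                            owner = p@user_id, group = grp,
                            row_index = r, column_index = co,
                            reagent = NA_real_, fields = numeric())
        keys[idx] <- .key("well", oids[idx])
    }
    list2env(setNames(recs, keys), envir = store@data$objects)
    rec <- .getObject(store, ref)
    rec$wells <- matrix(oids, rows, columns, byrow = TRUE)
    .setObject(store, ref, rec)
    ref
}

#' Well address labels
#'
#' `wellAddress()` turns 0-based (row, column) indices into the bench
#' convention letter-row + 1-based-number label ("A1"); rows beyond "Z" use
#' double letters ("AA", "AB", ...). `parseAddress()` is the inverse and
#' also accepts lowercase and zero-padded forms ("h012" -> (7, 11)).
#'
#' @param row_index,column_index 0-based grid indices.
#' @param address Label such as `"A1"` or `"P24"`.
#' @return A label, or a named numeric `c(row_index=, column_index=)`.
#' @examples
#' wellAddress(15, 23)      # "P24"
#' parseAddress("H12")      # row 7, column 11
#' @export
wellAddress <- function(row_index, column_index) {
    stopifnot(row_index >= 0, column_index >= 0)
    r <- as.integer(row_index)
    letters_out <- character(length(r))
    for (i in seq_along(r)) {
        n <- r[i] + 1L; s <- ""
        while (n > 0L) {                # bijective base-26
            n <- n - 1L
            s <- paste0(LETTERS[n %% 26L + 1L], s)
            n <- n %/% 26L
        }
        letters_out[i] <- s
    }
    paste0(letters_out, as.integer(column_index) + 1L)
}

#' @rdname wellAddress
#' @export
parseAddress <- function(address) {
    m <- regmatches(address, regexec("^([A-Za-z]+)0*([0-9]+)$", address))[[1L]]
    if (length(m) != 3L)
        stop("cannot parse well address '", address, "'")
    letters_part <- toupper(m[2L])
    r <- 0L
    for (ch in strsplit(letters_part, "")[[1L]])
        r <- r * 26L + match(ch, LETTERS)
    col <- as.integer(m[3L])
    if (col < 1L) stop("cannot parse well address '", address, "'")
    c(row_index = r - 1L, column_index = col - 1L)
}

#' Look up a well on a plate
#'
#' @param store An [HCSStore-class].
#' @param plate Plate [ObjectRef-class].
#' @param address Well label ("A1"), or give `row`/`column` 0-based indices.
#' @param row,column 0-based indices (alternative to `address`).
#' @return [ObjectRef-class] of the well.
#' @export
wellAt <- function(store, plate, address = NULL, row = NULL, column = NULL) {
    p <- .getObject(store, plate)
    if (!is.null(address)) {
        rc <- parseAddress(address)
        row <- rc[["row_index"]]; column <- rc[["column_index"]]
    }
    if (row < 0 || row >= p$rows || column < 0 || column >= p$columns)
        stop("bounds error: (", row, ",", column, ") outside ",
             p$rows, "x", p$columns, " plate")
    oid <- p$wells[row + 1L, column + 1L]
    if (is.na(oid)) stop("no well at (", row, ",", column, ")")
    objectRef("well", oid)
}

#' Create an image record
#'
#' Images are 5D (x, y, z, channel, time). The pixel source, when given, is
#' an external file path stored verbatim — pixel bytes are never copied
#' into the store. Channels are created alongside, one per `size_c`.
#'
#' @param store An [HCSStore-class].
#' @param name Image name.
#' @param size_x,size_y,size_z,size_c,size_t Positive dimensions.
#' @param channel_names Optional names, length `size_c`.
#' @param pixel_source Optional external file path (e.g. a TIFF plane).
#' @param acquisition Optional list of acquisition metadata
#'   (`objective_magnification` number, per-channel `exposure`
#'   [Quantity-class]s, ...).
#' @param as Acting principal.
#' @return [ObjectRef-class] of the new image.
#' @export
createImage <- function(store, name, size_x, size_y, size_z = 1, size_c = 1,
                        size_t = 1, channel_names = NULL, pixel_source = NULL,
                        acquisition = list(), as = NULL) {
    stopifnot(size_x >= 1, size_y >= 1, size_z >= 1, size_c >= 1, size_t >= 1)
    if (is.null(channel_names)) channel_names <- sprintf("ch%d", seq_len(size_c) - 1L)
    stopifnot(length(channel_names) == size_c)
    ref <- .putObject(store, "image",
                      list(name = name, size_x = size_x, size_y = size_y,
                           size_z = size_z, size_c = size_c, size_t = size_t,
                           channels = numeric(), rois = numeric(),
                           pixel_source = if (is.null(pixel_source)) NA_character_
                                          else pixel_source,
                           acquisition = acquisition), as = as)
    ch <- vapply(seq_len(size_c), function(i)
        .putObject(store, "channel",
                   list(index = i - 1L, name = channel_names[i],
                        emission = NULL), as = as)@oid, 0)
    rec <- .getObject(store, ref)
    rec$channels <- ch
    .setObject(store, ref, rec)
    ref
}

#' Create a reagent
#'
#' @param store An [HCSStore-class].
#' @param identifier Non-empty reagent ID (compound, siRNA, ...).
#' @param description Free text.
#' @param as Acting principal.
#' @return [ObjectRef-class] of the reagent.
#' @export
createReagent <- function(store, identifier, description = "", as = NULL) {
    if (!nzchar(identifier)) stop("reagent identifier must be non-empty")
    .putObject(store, "reagent",
               list(identifier = identifier, description = description), as = as)
}

#' @rdname createReagent
#' @param well Well ref to attach the reagent to.
#' @param reagent Reagent ref.
#' @export
setWellReagent <- function(store, well, reagent) {
    w <- .getObject(store, well); .getObject(store, reagent)
    w$reagent <- reagent@oid
    .setObject(store, well, w)
    invisible(well)
}

#' Add an imaged field to a well
#'
#' Fields are appended in order; the new field's index is the previous
#' field count, so indices stay contiguous 0..n-1. Exactly one image is
#' linked per field.
#'
#' @param store An [HCSStore-class].
#' @param well,image Existing refs.
#' @param as Acting principal (must be able to annotate the well).
#' @return [ObjectRef-class] of the new field.
#' @export
addField <- function(store, well, image, as = NULL) {
    w <- .getObject(store, well); .getObject(store, image)
    p <- .resolvePrincipal(store, as)
    if (!canAnnotate(store, p, well))
        stop("access error: '", p@user_id, "' may not modify this well")
    f <- .putObject(store, "field",
                    list(index = length(w$fields), image = image@oid), as = as)
    w$fields <- c(w$fields, f@oid)
    .setObject(store, well, w)
    f
}

#' Create a region of interest on an image
#'
#' Coordinates are 0-based pixel units, x right / y down; bounding boxes
#' are half-open. Geometry must lie within the image bounds, and a mask's
#' dimensions must match its bounding box.
#'
#' @param store An [HCSStore-class].
#' @param image Image ref the ROI delineates an object in.
#' @param shape_kind `"rectangle"`, `"ellipse"`, `"polygon"` or `"mask"`.
#' @param geometry For rectangle/ellipse/mask: `c(x, y, w, h)` bounding
#'   box; for polygon: a 2-column matrix of vertices.
#' @param mask Logical matrix (`h` rows x `w` cols) for `"mask"` ROIs.
#' @param z,c,t Optional plane attachment indices.
#' @param as Acting principal.
#' @return [ObjectRef-class] of the ROI.
#' @export
createROI <- function(store, image, shape_kind, geometry, mask = NULL,
                      z = NA, c = NA, t = NA, as = NULL) {
    img <- .getObject(store, image)
    shape_kind <- match.arg(shape_kind, c("rectangle", "ellipse", "polygon", "mask"))
    if (shape_kind == "polygon") {
        stopifnot(is.matrix(geometry), ncol(geometry) == 2L)
        if (any(geometry[, 1L] < 0) || any(geometry[, 1L] > img$size_x) ||
            any(geometry[, 2L] < 0) || any(geometry[, 2L] > img$size_y))
            stop("geometry outside image bounds")
    } else {
        stopifnot(length(geometry) == 4L)
        if (geometry[1L] < 0 || geometry[2L] < 0 ||
            geometry[1L] + geometry[3L] > img$size_x ||
            geometry[2L] + geometry[4L] > img$size_y)
            stop("geometry outside image bounds")
        if (shape_kind == "mask") {
            stopifnot(is.matrix(mask))
            if (nrow(mask) != geometry[4L] || ncol(mask) != geometry[3L])
                stop("mask dimensions must match the bounding box")
        }
    }
    ref <- .putObject(store, "roi",
                      list(image = image@oid, shape_kind = shape_kind,
                           geometry = geometry, mask = mask,
                           z = z, c = c, t = t), as = as)
    img <- .getObject(store, image)
    img$rois <- c(img$rois, ref@oid)
    .setObject(store, image, img)
    ref
}

## which otypes are reachable downward from each container type
.REACHABLE <- list(
    screen = c("plate", "well", "field", "image", "channel", "reagent", "roi"),
    plate = c("well", "field", "image", "channel", "reagent", "roi"),
    well = c("field", "image", "channel", "reagent", "roi"),
    field = c("image", "channel", "roi"),
    image = c("channel", "roi"))

#' Count reachable descendants of a container
#'
#' Traverses the containment hierarchy (screen -> plate -> well -> field ->
#' image -> channel, with reagents hanging off screens and wells and ROIs
#' off images) and counts objects of the target type.
#'
#' @param store An [HCSStore-class].
#' @param container [ObjectRef-class] of a container object.
#' @param target_otype Object type to count.
#' @return Integer count.
#' @export
countDescendants <- function(store, container, target_otype) {
    o <- .getObject(store, container)
    reach <- .REACHABLE[[o$otype]]
    if (is.null(reach) || !(target_otype %in% reach))
        stop("domain error: '", target_otype, "' is not reachable from a ",
             o$otype)
    n <- 0L
    count <- function(o) {
        switch(o$otype,
            screen = {
                if (target_otype == "reagent") n <<- n + length(o$reagent_refs)
                for (p in o$plate_refs)
                    count(.getObject(store, objectRef("plate", p)))
            },
            plate = {
                w <- o$wells[!is.na(o$wells)]
                if (target_otype == "well") n <<- n + length(w)
                else for (x in w) count(.getObject(store, objectRef("well", x)))
            },
            well = {
                if (target_otype == "reagent") {
                    if (!is.na(o$reagent)) n <<- n + 1L
                } else if (target_otype == "field") {
                    n <<- n + length(o$fields)
                } else for (f in o$fields)
                    count(.getObject(store, objectRef("field", f)))
            },
            field = {
                if (target_otype == "image") n <<- n + 1L
                else count(.getObject(store, objectRef("image", o$image)))
            },
            image = {
                if (target_otype == "channel") n <<- n + length(o$channels)
                else if (target_otype == "roi") n <<- n + length(o$rois)
            })
    }
    count(o)
    n
}

#' Read an object's metadata record
#'
#' Returns the stored record (names, dimensions, containment refs, owner
#' and group) after a read-permission check — a principal who cannot read
#' the object gets an access error, not an empty record.
#'
#' @param store An [HCSStore-class].
#' @param ref [ObjectRef-class].
#' @param as Acting principal.
#' @return Named list with the object's fields.
#' @export
objectInfo <- function(store, ref, as = NULL) {
    o <- .getObject(store, ref)
    p <- .resolvePrincipal(store, as)
    if (!canRead(store, p, ref))
        stop("access error: '", p@user_id, "' may not read <",
             .key(ref@otype, ref@oid), ">")
    o
}
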