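## Seeded generator of complete synthetic screens, so every storage
## strategy is exercisable with no external data. The RNG is R's
## Mersenne-Twister with inversion sampling for normals, seeded once from
## the config, so a given (config, seed) reproduces the identical store
## structure and byte-identical feature tables.

.GEN_APPEND_CHUNK <- 1e6

#' @rdname ScreenConfig-class
#' @param n_plates,plate_format,fields_per_well,channels,n_features,seed
#'   See [ScreenConfig-class].
#' @param cells `list(kind = "constant", k = )` or
#'   `list(kind = "poisson", lambda = )`.
#' @param feature_mean,feature_sd Gaussian feature parameters, recycled
#'   over features.
#' @export
screenConfig <- function(n_plates = 1, plate_format = 384,
                         fields_per_well = 5, channels = 3,
                         cells = list(kind = "constant", k = 50),
                         n_features = 25, feature_mean = 0, feature_sd = 1,
                         seed) {
    new("ScreenConfig", n_plates = n_plates, plate_format = plate_format,
        fields_per_well = fields_per_well, channels = channels,
        cells = cells, n_features = n_features,
        feature_mean = rep_len(feature_mean, max(n_features, 1L)),
        feature_sd = rep_len(feature_sd, max(n_features, 1L)), seed = seed)
}

## bulk ROI insertion (rectangles already validated against image bounds)
.bulkROIs <- function(store, imageRef, x0, y0, w, h, as = NULL) {
    k <- length(x0)
    if (!k) return(numeric())
    oids <- .newOids(store, "roi", k)
    p <- .resolvePrincipal(store, as)
    grp <- if (length(p@group_ids)) p@group_ids[[1L]] else "default"
    recs <- lapply(seq_len(k), function(i)
        list(otype = "roi", oid = oids[i], owner = p@user_id, group = grp,
             image = imageRef@oid, shape_kind = "rectangle",
             geometry = c(x0[i], y0[i], w[i], h[i]), mask = NULL,
             z = NA, c = NA, t = NA))
    list2env(setNames(recs, vapply(oids, function(o) .key("roi", o), "")),
             envir = store@data$objects)
    img <- .getObject(store, imageRef)
    img$rois <- c(img$rois, oids)
    .setObject(store, imageRef, img)
    oids
}

#' Generate a synthetic screen
#'
#' Populates the store with a screen, its plates (all wells with one
#' reagent each), fields, images, channels and one rectangular ROI per
#' simulated cell, and writes per-cell Gaussian feature values into an
#' HDF5 feature table. The long layout holds one row per (ROI, channel,
#' feature); the wide layout one row per ROI with a column per
#' feature x channel (see [wideFeatureSchema()]). Images are 512 x 512
#' with one z plane and one timepoint; ROIs are 20 x 20 rectangles at
#' uniformly drawn in-bounds positions.
#'
#' @param store An [HCSStore-class].
#' @param config A [screenConfig()] (the seed lives there).
#' @param table_path Path for the long-format HDF5 table (`NULL` to skip).
#' @param layout `"long"`, `"wide"`, or `"both"`.
#' @param wide_path Path for the wide-format table (required for
#'   `"wide"`/`"both"`).
#' @param as Acting principal.
#' @return Summary list: `screen` (ref), `plates` (refs), `wells`,
#'   `images`, `rois`, `feature_rows`, `table` / `wide_table`
#'   (store refs of registered tables or `NULL`).
#' @examples
#' st <- initStore(tempfile("store"))
#' cfg <- screenConfig(plate_format = 96, fields_per_well = 1,
#'                     channels = 2, cells = list(kind = "constant", k = 3),
#'                     n_features = 4, seed = 7)
#' s <- generateScreen(st, cfg, tempfile(fileext = ".h5"))
#' s$feature_rows   # 96 * 1 * 3 * 2 * 4
#' @export
generateScreen <- function(store, config, table_path = NULL,
                           layout = c("long", "wide", "both"),
                           wide_path = NULL, as = NULL) {
    layout <- match.arg(layout)
    validObject(config)
    if (layout != "long" && is.null(wide_path))
        stop("wide_path needed for layout '", layout, "'")
    set.seed(config@seed, kind = "Mersenne-Twister",
             normal.kind = "Inversion", sample.kind = "Rejection")

    ch <- as.integer(config@channels); nf <- as.integer(config@n_features)
    screen <- createScreen(store, sprintf("synthetic-screen-%d", config@seed),
                           as = as)
    plates <- list()
    roi_ids <- list(); roi_img <- list(); roi_well <- list()
    n_wells <- 0L; n_images <- 0L
    sx <- 512L; sy <- 512L; rw <- 20L; rh <- 20L
    well_counter <- 0L

    for (pi in seq_len(config@n_plates)) {
        plate <- createPlate(store, sprintf("plate-%d", pi),
                             format = config@plate_format, as = as)
        addPlateToScreen(store, screen, plate)
        plates[[pi]] <- plate
        prec <- .getObject(store, plate)
        for (r in seq_len(prec$rows) - 1L) for (co in seq_len(prec$columns) - 1L) {
            well <- objectRef("well", prec$wells[r + 1L, co + 1L])
            n_wells <- n_wells + 1L
            well_counter <- well_counter + 1L
            reagent <- createReagent(store,
                                     sprintf("compound-%04d", well_counter),
                                     as = as)
            wrec <- .getObject(store, screen)
            wrec$reagent_refs <- c(wrec$reagent_refs, reagent@oid)
            .setObject(store, screen, wrec)
            setWellReagent(store, well, reagent)
            addr <- wellAddress(r, co)
            for (fi in seq_len(config@fields_per_well) - 1L) {
                image <- createImage(store,
                                     sprintf("plate-%d/%s/field-%d", pi, addr, fi),
                                     size_x = sx, size_y = sy, size_c = ch,
                                     as = as)
                addField(store, well, image, as = as)
                n_images <- n_images + 1L
                k <- if (config@cells$kind == "constant") config@cells$k
                     else stats::rpois(1L, config@cells$lambda)
                x0 <- floor(stats::runif(k, 0, sx - rw))
                y0 <- floor(stats::runif(k, 0, sy - rh))
                ids <- .bulkROIs(store, image, x0, y0, rep(rw, k), rep(rh, k),
                                 as = as)
                roi_ids[[length(roi_ids) + 1L]] <- ids
                roi_img[[length(roi_img) + 1L]] <- rep(image@oid, k)
                roi_well[[length(roi_well) + 1L]] <- rep(well@oid, k)
            }
        }
    }

    rois <- unlist(roi_ids); imgs <- unlist(roi_img); wells <- unlist(roi_well)
    n_rois <- length(rois)
    n_long <- n_rois * ch * nf
    feat_idx <- if (n_long) rep(seq_len(nf), times = n_rois * ch) else integer()
    values <- if (n_long)
        stats::rnorm(n_long, mean = config@feature_mean[feat_idx],
                     sd = config@feature_sd[feat_idx])
    else numeric()

    tab_ref <- NULL; wide_ref <- NULL; n_rows_written <- 0
    if (!is.null(table_path) && layout %in% c("long", "both")) {
        tab <- createTable(table_path, longFeatureSchema())
        if (n_long) {
            long_roi <- rep(rois, each = ch * nf)
            long_img <- rep(imgs, each = ch * nf)
            long_well <- rep(wells, each = ch * nf)
            long_ch <- rep(rep(seq_len(ch), each = nf), times = n_rois)
            start <- 1
            while (start <= n_long) {
                end <- min(start + .GEN_APPEND_CHUNK - 1, n_long)
                ix <- start:end
                appendRows(tab, list(well = long_well[ix], image = long_img[ix],
                                     roi = long_roi[ix], channel = long_ch[ix],
                                     feature = feat_idx[ix],
                                     value = values[ix]))
                start <- end + 1
            }
        }
        n_rows_written <- rowCount(tab)
        tab_ref <- attachTable(store, table_path,
                               target = if (length(plates)) plates[[1L]] else screen,
                               as = as)
    }
    if (layout %in% c("wide", "both")) {
        wtab <- createTable(wide_path, wideFeatureSchema(ch, nf))
        if (n_rois) {
            block <- list(well = wells, image = imgs, roi = rois)
            for (f in seq_len(nf)) for (cc in seq_len(ch))
                block[[sprintf("feature_%d_ch_%d", f, cc)]] <-
                    values[(seq_len(n_rois) - 1L) * ch * nf + (cc - 1L) * nf + f]
            appendRows(wtab, block)
        }
        wide_ref <- attachTable(store, wide_path,
                                target = if (length(plates)) plates[[1L]] else screen,
                                as = as)
        if (layout == "wide") n_rows_written <- rowCount(wtab)
    }

    list(screen = screen, plates = plates, wells = n_wells,
         images = n_images, rois = n_rois, feature_rows = n_rows_written,
         table = tab_ref, wide_table = wide_ref)
}

#' Generate a bulk-annotation sheet for a synthetic plate
#'
#' Writes a CSV with one data row per well of the config's plate format,
#' carrying the well's reagent ID plus two metadata columns (`Cell line`,
#' `Temperature [°C]`) — a ready-made input for [loadSheet()].
#'
#' @param config A [screenConfig()].
#' @param path Output CSV path.
#' @return Number of data rows written.
#' @export
generateSheet <- function(config, path) {
    g <- .PLATE_GRIDS[[as.character(config@plate_format)]]
    rows <- if (config@n_plates < 1) 0L else g[1L]
    cols <- if (config@n_plates < 1) 0L else g[2L]
    lines <- character()
    i <- 0L
    for (r in seq_len(rows) - 1L) for (co in seq_len(cols) - 1L) {
        i <- i + 1L
        lines[i] <- sprintf("%s,compound-%04d,U2OS,37", wellAddress(r, co), i)
    }
    writeLines(c("Well,Reagent,Cell line,Temperature [°C]", lines), path,
               useBytes = FALSE)
    length(lines)
}

#' Render a small synthetic pixel plane for an ROI layout
#'
#' On-request pixel simulation: Gaussian intensity blobs centred on each
#' ROI rectangle over a dark background, returned as a plane suitable for
#' [planeStats()] and [renderThumbnail()]. Deterministic given the ROI
#' layout (no RNG involved).
#'
#' @param store An [HCSStore-class].
#' @param image Image [ObjectRef-class] with ROIs.
#' @param peak Peak blob intensity.
#' @param background Background level.
#' @return Numeric matrix `size_y x size_x`.
#' @export
renderSyntheticPlane <- function(store, image, peak = 1000, background = 100) {
    img <- .getObject(store, image)
    m <- matrix(background, img$size_y, img$size_x)
    xs <- matrix(rep(seq_len(img$size_x), each = img$size_y), img$size_y)
    ys <- matrix(rep(seq_len(img$size_y), img$size_x), img$size_y)
    for (roid in img$rois) {
        roi <- .getObject(store, objectRef("roi", roid))
        g <- roi$geometry
        cx <- g[1L] + g[3L] / 2; cy <- g[2L] + g[4L] / 2
        s2 <- (g[3L] / 4)^2
        m <- m + peak * exp(-((xs - cx)^2 + (ys - cy)^2) / (2 * s2))
    }
    m
}
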