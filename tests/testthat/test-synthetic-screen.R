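test_that("summary counts obey the closed-form arithmetic", {
    st <- newTestStore()
    cfg <- screenConfig(plate_format = 96, fields_per_well = 2, channels = 2,
                        cells = list(kind = "constant", k = 3),
                        n_features = 4, seed = 11)
    f <- tempfile(fileext = ".h5")
    s <- generateScreen(st, cfg, f)
    expect_equal(s$wells, 96)
    expect_equal(s$images, 96 * 2)
    expect_equal(s$rois, 96 * 2 * 3)
    expect_equal(s$feature_rows, 96 * 2 * 3 * 2 * 4)
    # counts re-derived from the store itself
    p <- s$plates[[1]]
    expect_equal(countDescendants(st, p, "image"), s$images)
    expect_equal(countDescendants(st, p, "roi"), s$rois)
    expect_equal(countDescendants(st, p, "reagent"), 96)
    expect_equal(rowCount(openTable(f)), s$feature_rows)
})

test_that("an empty configuration generates nothing", {
    st <- newTestStore()
    cfg <- screenConfig(n_plates = 0, seed = 1)
    s <- generateScreen(st, cfg, tempfile(fileext = ".h5"))
    expect_equal(s$wells, 0)
    expect_equal(s$images, 0)
    expect_equal(s$rois, 0)
    expect_equal(s$feature_rows, 0)
})

test_that("identical seeds give byte-identical tables, different seeds differ", {
    mk <- function(seed) {
        f <- tempfile(fileext = ".h5")
        generateScreen(newTestStore(),
                       screenConfig(plate_format = 96, fields_per_well = 1,
                                    channels = 2,
                                    cells = list(kind = "constant", k = 4),
                                    n_features = 3, seed = seed), f)
        readBin(f, "raw", file.size(f))
    }
    b1 <- mk(101); b2 <- mk(101); b3 <- mk(202)
    expect_identical(b1, b2)
    expect_false(identical(b1, b3))
})

test_that("Poisson cell counts still satisfy rows = rois x channels x features", {
    st <- newTestStore()
    cfg <- screenConfig(plate_format = 96, fields_per_well = 1, channels = 2,
                        cells = list(kind = "poisson", lambda = 5),
                        n_features = 3, seed = 13)
    f <- tempfile(fileext = ".h5")
    s <- generateScreen(st, cfg, f)
    expect_equal(s$feature_rows, s$rois * 2 * 3)
    # rois equal the sum of per-image ROI counts in the store
    p <- s$plates[[1]]
    expect_equal(countDescendants(st, p, "roi"), s$rois)
})

test_that("ROI rectangles lie inside their image bounds", {
    st <- newTestStore()
    cfg <- screenConfig(plate_format = 96, fields_per_well = 1, channels = 1,
                        cells = list(kind = "constant", k = 10),
                        n_features = 1, seed = 3)
    s <- generateScreen(st, cfg, tempfile(fileext = ".h5"))
    p <- objectInfo(st, s$plates[[1]])
    w <- objectInfo(st, objectRef("well", p$wells[1, 1]))
    fld <- objectInfo(st, objectRef("field", w$fields[1]))
    img <- objectInfo(st, objectRef("image", fld$image))
    for (roid in img$rois) {
        g <- objectInfo(st, objectRef("roi", roid))$geometry
        expect_gte(g[1], 0); expect_gte(g[2], 0)
        expect_lte(g[1] + g[3], img$size_x)
        expect_lte(g[2] + g[4], img$size_y)
    }
})

test_that("table backlinks recover a generated ROI's measurements", {
    st <- newTestStore()
    cfg <- screenConfig(plate_format = 96, fields_per_well = 1, channels = 2,
                        cells = list(kind = "constant", k = 3),
                        n_features = 4, seed = 17)
    f <- tempfile(fileext = ".h5")
    s <- generateScreen(st, cfg, f)
    tab <- getTable(st, s$table)
    p <- objectInfo(st, s$plates[[1]])
    w <- objectInfo(st, objectRef("well", p$wells[1, 1]))
    fld <- objectInfo(st, objectRef("field", w$fields[1]))
    img <- objectInfo(st, objectRef("image", fld$image))
    rows <- backlink(tab, "roi", objectRef("roi", img$rois[1]))
    expect_length(rows, 2 * 4)     # channels x features rows per ROI
    got <- readRows(tab, c("roi", "channel", "feature"), rows[1], rows[1] + 8)
    expect_true(all(got$roi == img$rois[1]))
    expect_equal(sort(unique(got$channel)), c(1, 2))
})

test_that("generated sheets round trip through bulk annotation", {
    cfg <- screenConfig(plate_format = 96, seed = 19)
    f <- tempfile(fileext = ".csv")
    expect_equal(generateSheet(cfg, f), 96)
    st <- newTestStore()
    p <- createPlate(st, "p", format = 96)
    rep <- loadSheet(st, f, p)
    expect_equal(rep$annotations_created, 96)
    expect_length(rep$unmatched, 0)
    a <- getAnnotations(st, wellAt(st, p, "A1"),
                        namespace = "hcstore:/bulk_annotations")[[1]]
    expect_identical(a@pairs$key, c("Reagent", "Cell line", "Temperature"))
    expect_identical(a@pairs$unit[3], "°C")
    expect_equal(generateSheet(screenConfig(n_plates = 0, seed = 1),
                               tempfile(fileext = ".csv")), 0)
})

test_that("synthetic planes carry blob signal over background", {
    st <- newTestStore()
    img <- createImage(st, "img", 64, 64)
    createROI(st, img, "rectangle", c(20, 20, 20, 20))
    plane <- renderSyntheticPlane(st, img, peak = 1000, background = 100)
    expect_equal(dim(plane), c(64, 64))
    s <- planeStats(plane)
    expect_gte(unname(s["min"]), 100)
    expect_gt(unname(s["max"]), 1000)
    # deterministic: same layout, same plane
    expect_identical(renderSyntheticPlane(st, img), plane)
})
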