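test_that("standard plate formats instantiate the full SBS grid", {
    st <- newTestStore()
    cases <- list(`96` = c(8, 12), `384` = c(16, 24), `1536` = c(32, 48))
    for (fmt in names(cases)) {
        p <- createPlate(st, paste0("p", fmt), format = as.numeric(fmt))
        rec <- objectInfo(st, p)
        expect_equal(c(rec$rows, rec$columns), cases[[fmt]])
        # enumerate the well grid independently of countDescendants
        expect_equal(sum(!is.na(rec$wells)), prod(cases[[fmt]]))
        expect_equal(countDescendants(st, p, "well"), as.numeric(fmt))
    }
    expect_error(createPlate(st, "bad", format = 42), "format error")
})

test_that("well addresses follow letter+number convention and invert", {
    expect_identical(wellAddress(0, 0), "A1")
    # last cell of a 16x24 grid, checked against full enumeration
    labels <- outer(0:15, 0:23, wellAddress)
    expect_identical(labels[16, 24], "P24")
    expect_identical(wellAddress(15, 23), labels[16, 24])
    expect_equal(unname(parseAddress("H12")), c(7, 11))
    expect_equal(unname(parseAddress("H012")), c(7, 11))  # zero-padded
    expect_equal(unname(parseAddress("a1")), c(0, 0))     # case-insensitive
    expect_error(parseAddress("12H"), "cannot parse")
})

test_that("addresses and parsing are mutual inverses over the 32x48 grid", {
    for (r in 0:31) for (co in 0:47) {
        rc <- parseAddress(wellAddress(r, co))
        expect_identical(unname(rc), c(r, co))
    }
    # double-letter rows appear beyond Z
    expect_identical(wellAddress(26, 0), "AA1")
})

test_that("fields append with contiguous indices and one image each", {
    st <- newTestStore()
    p <- createPlate(st, "p", format = 96)
    w <- wellAt(st, p, "B3")
    for (i in 1:5) {
        img <- createImage(st, sprintf("img%d", i), 64, 64)
        f <- addField(st, w, img)
        expect_equal(objectInfo(st, f)$index, i - 1)
    }
    expect_equal(length(objectInfo(st, w)$fields), 5)
    # dangling refs are an error
    expect_error(addField(st, objectRef("well", 99999),
                          createImage(st, "x", 8, 8)), "reference error")
})

test_that("descendant counts agree with independent traversal", {
    st <- newTestStore()
    p <- createPlate(st, "p", format = 96)
    rec <- objectInfo(st, p)
    nfield <- 0
    for (oid in rec$wells[1:10]) {
        w <- objectRef("well", oid)
        k <- sample(0:3, 1)
        for (i in seq_len(k))
            addField(st, w, createImage(st, "i", 32, 32, size_c = 2))
        nfield <- nfield + k
    }
    # independent tally: sum of per-well field counts
    tally <- sum(vapply(rec$wells[!is.na(rec$wells)], function(oid)
        length(objectInfo(st, objectRef("well", oid))$fields), 0))
    expect_equal(countDescendants(st, p, "image"), tally)
    expect_equal(countDescendants(st, p, "image"), nfield)
    expect_equal(countDescendants(st, p, "channel"), 2 * nfield)
    expect_error(countDescendants(st, p, "screen"), "domain error")
    s <- createScreen(st, "empty")
    expect_equal(countDescendants(st, s, "plate"), 0)
})

test_that("object IDs are stable and never reused after deletion", {
    st <- newTestStore()
    r1 <- createReagent(st, "cmp-1")
    deleteObject(st, r1)
    expect_error(objectInfo(st, r1), "reference error")
    r2 <- createReagent(st, "cmp-2")
    expect_gt(r2@oid, r1@oid)
})

test_that("deletion is restricted unless cascading", {
    st <- newTestStore()
    p <- createPlate(st, "p", format = 96)
    w <- wellAt(st, p, "A1")
    img <- createImage(st, "img", 32, 32)
    addField(st, w, img)
    # image is referenced by the field: restricted delete fails
    expect_error(deleteObject(st, img), "inbound")
    # plate holds wells: cascade removes the whole subtree
    n <- deleteObject(st, p, cascade = TRUE)
    expect_gt(n, 96)
    expect_error(wellAt(st, p, "A1"), "reference error")
    expect_error(annotate(st, w, tagAnnotation("gone")), "reference error")
})

test_that("ROI geometry is validated against image bounds", {
    st <- newTestStore()
    img <- createImage(st, "img", 100, 80)
    roi <- createROI(st, img, "rectangle", c(10, 10, 20, 20))
    expect_equal(objectInfo(st, roi)$geometry, c(10, 10, 20, 20))
    expect_error(createROI(st, img, "rectangle", c(90, 10, 20, 20)), "bounds")
    expect_error(createROI(st, img, "mask", c(0, 0, 4, 4),
                           mask = matrix(TRUE, 3, 4)), "mask dimensions")
    # mask matching its bbox is accepted
    expect_s4_class(createROI(st, img, "mask", c(0, 0, 4, 3),
                              mask = matrix(TRUE, 3, 4)), "ObjectRef")
})

test_that("store state survives a save/open round trip", {
    st <- newTestStore()
    p <- createPlate(st, "p", format = 384)
    w <- wellAt(st, p, "P24")
    annotate(st, w, mapAnnotation(c("Cell line" = "U2OS")))
    saveStore(st)
    st2 <- openStore(st@path)
    expect_equal(countDescendants(st2, p, "well"), 384)
    anns <- getAnnotations(st2, wellAt(st2, p, "P24"))
    expect_length(anns, 1)
    expect_identical(anns[[1]]@pairs$value, "U2OS")
})
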