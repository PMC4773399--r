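test_that("map annotations attach, link and read back with units", {
    st <- newTestStore()
    p <- createPlate(st, "p", format = 96)
    w <- wellAt(st, p, "A1")
    annotate(st, w, mapAnnotation(c("Cell line" = "U2OS")))
    img <- createImage(st, "img", 32, 32)
    annotate(st, img, mapAnnotation(
        data.frame(key = "Temperature", value = "37", unit = "°C")))
    anns <- getAnnotations(st, w)
    expect_length(anns, 1)
    expect_identical(anns[[1]]@pairs$value, "U2OS")
    ianns <- getAnnotations(st, img)
    expect_identical(ianns[[1]]@pairs$unit, "°C")
    expect_error(annotate(st, objectRef("well", 12345),
                          tagAnnotation("x")), "reference error")
})

test_that("namespace filtering is exact and order is link-creation order", {
    st <- newTestStore()
    s <- createScreen(st, "s")
    a1 <- tempfile(fileext = ".txt"); writeLines("alpha", a1)
    a2 <- tempfile(fileext = ".txt"); writeLines("beta", a2)
    attachFile(st, s, a1, namespace = "N1")
    attachFile(st, s, a2, namespace = "N2")
    n1 <- getAnnotations(st, s, namespace = "N1")
    expect_length(n1, 1)
    expect_identical(n1[[1]]@filename, basename(a1))
    expect_length(getAnnotations(st, s, namespace = "unknown"), 0)
    expect_length(getAnnotations(st, createScreen(st, "bare")), 0)
    both <- getAnnotations(st, s)
    expect_identical(vapply(both, function(a) a@namespace, ""), c("N1", "N2"))
})

test_that("map queries match key and value exactly", {
    st <- newTestStore()
    p <- createPlate(st, "p", format = 96)
    for (a in c("A1", "B1", "C1"))
        annotate(st, wellAt(st, p, a), mapAnnotation(c("Cell line" = "U2OS")))
    annotate(st, wellAt(st, p, "D1"), mapAnnotation(c("Cell line" = "HeLa")))
    expect_equal(nrow(queryMap(st, "Cell line", "U2OS")), 3)
    expect_equal(nrow(queryMap(st, "Cell line")), 4)
    expect_equal(nrow(queryMap(st, "cell line")), 0)      # case-sensitive
    expect_equal(nrow(queryMap(newTestStore(), "anything")), 0)
})

test_that("map queries agree with a linear-scan oracle on random stores", {
    for (seed in 1:8) {
        fx <- randomAnnotatedStore(seed)
        for (key in c("Cell line", "Stain", "absent"))
            expect_equal(queryMap(fx$store, key),
                         oracleQueryMap(fx$shadow, key), info = paste(seed, key))
        expect_equal(queryMap(fx$store, "Cell line", "U2OS"),
                     oracleQueryMap(fx$shadow, "Cell line", "U2OS"))
    }
})

test_that("pair order and duplicate keys survive store round trips", {
    st <- newTestStore()
    s <- createScreen(st, "s")
    pairs <- data.frame(key = c("b", "a", "a", "z"),
                        value = c("1", "2", "3", "4"),
                        unit = c(NA, "nm", NA, "s"), stringsAsFactors = FALSE)
    annotate(st, s, mapAnnotation(pairs))
    saveStore(st)
    st2 <- openStore(st@path)
    got <- getAnnotations(st2, s)[[1]]@pairs
    expect_identical(got$key, pairs$key)
    expect_identical(got$value, pairs$value)
    expect_identical(got$unit, pairs$unit)
})

test_that("file payloads round trip byte-for-byte with matching checksums", {
    st <- newTestStore()
    s <- createScreen(st, "s")
    bin <- tempfile()
    bytes <- as.raw(c(0, 255, 10, 13, 26, sample(0:255, 64, replace = TRUE)))
    writeBin(bytes, bin)
    r1 <- attachFile(st, s, bin, namespace = "N")
    r2 <- attachFile(st, s, bin, namespace = "N")
    expect_false(identical(r1@oid, r2@oid))        # distinct annotations
    a <- getAnnotations(st, s)
    expect_identical(a[[1]]@checksum, a[[2]]@checksum)
    expect_identical(annotationPayload(st, r1), bytes)
    out <- exportFileAnnotation(st, r1, tempdir())
    expect_identical(readBin(out, "raw", file.size(out)), bytes)
    expect_error(attachFile(st, s, tempfile("nope")), "I/O error")
})

test_that("mimetypes are inferred from extensions with a binary fallback", {
    st <- newTestStore()
    s <- createScreen(st, "s")
    f1 <- tempfile(fileext = ".txt"); writeLines("x", f1)
    f2 <- tempfile(fileext = ".zzz"); writeLines("x", f2)
    attachFile(st, s, f1)
    a1 <- getAnnotations(st, s)[[1]]
    expect_identical(a1@mimetype, "text/plain")
    attachFile(st, s, f2)
    a2 <- getAnnotations(st, s)[[2]]
    expect_identical(a2@mimetype, "application/octet-stream")
})

test_that("a shared annotation links to many targets but not twice to one", {
    st <- newTestStore()
    s1 <- createScreen(st, "s1"); s2 <- createScreen(st, "s2")
    ref <- annotate(st, s1, tagAnnotation("control"))
    annotate(st, s2, ref)
    expect_length(getAnnotations(st, s2), 1)
    expect_error(annotate(st, s1, ref), "duplicate")
})
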