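smallSchema <- function() {
    tableSchema(columnSpec("roi", "roi_ref"),
                columnSpec("channel", "int64"),
                columnSpec("value", "float64"),
                columnSpec("ok", "bool"),
                columnSpec("label", "string", width = 8))
}

smallBlock <- function(n, seed) {
    set.seed(seed)
    list(roi = sample(1:50, n, replace = TRUE),
         channel = sample(1:3, n, replace = TRUE),
         value = round(rnorm(n), 6),
         ok = sample(c(TRUE, FALSE), n, replace = TRUE),
         label = paste0("c", sample(1:20, n, replace = TRUE)))
}

test_that("tables create with frozen schemas and reopen identically", {
    f <- tempfile(fileext = ".h5")
    tab <- createTable(f, smallSchema())
    expect_equal(rowCount(tab), 0)
    tab2 <- openTable(f)
    expect_identical(vapply(tab2@schema@columns, function(c) c@name, ""),
                     vapply(smallSchema()@columns, function(c) c@name, ""))
    expect_identical(vapply(tab2@schema@columns, function(c) c@kind, ""),
                     vapply(smallSchema()@columns, function(c) c@kind, ""))
    expect_error(createTable(f, smallSchema()), "collision error")
    expect_error(tableSchema(columnSpec("x", "int64"), columnSpec("x", "float64")),
                 "duplicate")
    expect_error(tableSchema(), "at least one column")
    # the wide per-cell layout carries 3 reference + 75 feature columns
    expect_length(wideFeatureSchema(3, 25)@columns, 78)
})

test_that("appends assign contiguous indices and reads return exact values", {
    f <- tempfile(fileext = ".h5")
    tab <- createTable(f, smallSchema())
    b <- smallBlock(2, 1)
    expect_equal(appendRows(tab, b), c(first = 0, n = 2))
    expect_equal(appendRows(tab, smallBlock(3, 2)), c(first = 2, n = 3))
    expect_equal(rowCount(tab), 5)
    got <- readRows(tab, names(b), 0, 2)
    expect_identical(got$value, b$value)
    expect_identical(got$label, b$label)
    expect_identical(got$ok, b$ok)
    expect_equal(got$roi, b$roi)
    # zero-length range and bounds checks
    z <- readRows(tab, "value", 3, 3)
    expect_length(z$value, 0)
    expect_error(readRows(tab, "value", 0, 99), "bounds error")
    expect_error(readRows(tab, "nope", 0, 1), "name error")
})

test_that("malformed blocks are rejected and leave the table unchanged", {
    f <- tempfile(fileext = ".h5")
    tab <- createTable(f, smallSchema())
    appendRows(tab, smallBlock(4, 3))
    b <- smallBlock(2, 4)
    expect_error(appendRows(tab, b[-1]), "shape error")                # missing col
    b2 <- b; b2$value <- b2$value[1]
    expect_error(appendRows(tab, b2), "shape error")                   # ragged
    b3 <- b; b3$channel <- c(1.5, 2)
    expect_error(appendRows(tab, b3), "type error")                    # non-integer
    b4 <- b; b4$label <- c("muchtoolongforwidth", "x")
    expect_error(appendRows(tab, b4), "type error")                    # overwide
    b5 <- b; b5$ok <- c(TRUE, NA)
    expect_error(appendRows(tab, b5), "type error")                    # missing bool
    expect_equal(rowCount(tab), 4)                                     # atomic
    expect_equal(rowCount(openTable(f)), 4)
    # float64 columns accept NaN as the missing representation
    b$value <- c(NaN, 1)
    appendRows(tab, b)
    expect_true(is.nan(readRows(tab, "value", 4, 5)$value))
})

test_that("appended blocks survive close/reopen across 30 fuzzed cycles", {
    f <- tempfile(fileext = ".h5")
    tab <- createTable(f, smallSchema())
    shadow <- NULL
    for (i in 1:30) {
        b <- smallBlock(sample(1:40, 1), 100 + i)
        appendRows(tab, b)
        shadow <- if (is.null(shadow)) b
                  else Map(c, shadow, b)
        tab <- openTable(f)                 # fresh handle every cycle
        got <- readRows(tab)
        expect_equal(got$value, shadow$value)
        expect_identical(got$label, shadow$label)
    }
})

test_that("restricted queries equal a brute-force scan", {
    f <- tempfile(fileext = ".h5")
    tab <- createTable(f, smallSchema())
    expect_length(queryRows(tab, tableCondition("value", ">", 0)), 0)  # empty table
    b <- smallBlock(1000, 99)
    appendRows(tab, b)
    conds <- list(tableCondition("value", ">", 0.5),
                  tableCondition("channel", "==", 1))
    expect_equal(queryRows(tab, conds), oracleScan(b, conds))
    expect_equal(queryRows(tab, tableCondition("label", "!=", "c1")),
                 oracleScan(b, list(tableCondition("label", "!=", "c1"))))
    expect_equal(queryRows(tab, tableCondition("ok", "==", TRUE)),
                 oracleScan(b, list(tableCondition("ok", "==", TRUE))))
    # tautology returns every index
    expect_equal(queryRows(tab, tableCondition("channel", ">=", 1)),
                 as.double(0:999))
    expect_error(queryRows(tab, tableCondition("nope", "==", 1)),
                 "condition error")
    expect_error(queryRows(tab, tableCondition("value", ">", "high")),
                 "condition error")
})

test_that("backlinks recover exactly the rows of a source object", {
    f <- tempfile(fileext = ".h5")
    tab <- createTable(f, tableSchema(columnSpec("roi", "roi_ref"),
                                      columnSpec("v", "float64")))
    # 50 rows per ROI group, by construction
    appendRows(tab, list(roi = rep(c(7, 9, 11), each = 50),
                         v = as.double(1:150)))
    expect_equal(backlink(tab, "roi", objectRef("roi", 9)), as.double(50:99))
    expect_length(backlink(tab, "roi", objectRef("roi", 12345)), 0)
    expect_equal(backlink(tab, "roi", objectRef("roi", 7)),
                 queryRows(tab, tableCondition("roi", "==", 7)))
    expect_error(backlink(tab, "roi", objectRef("image", 9)), "type error")
})

test_that("CSV export reproduces the stored rows", {
    f <- tempfile(fileext = ".h5")
    tab <- createTable(f, smallSchema())
    b <- smallBlock(20, 5)
    appendRows(tab, b)
    out <- tempfile(fileext = ".csv")
    expect_equal(exportTableCSV(tab, out), 20)
    back <- utils::read.csv(out, stringsAsFactors = FALSE)
    expect_equal(back$value, b$value)
    expect_identical(back$label, b$label)
})

test_that("store-registered tables respect linked-object permissions", {
    st <- newTestStore()
    addPrincipal(st, "owner", "lab")
    addPrincipal(st, "outsider", "other")
    p <- createPlate(st, "p", format = 96, as = "owner")
    f <- tempfile(fileext = ".h5")
    createTable(f, tableSchema(columnSpec("v", "float64")))
    tref <- attachTable(st, f, target = p, as = "owner")
    expect_s4_class(getTable(st, tref, as = "owner"), "FeatureTable")
    expect_error(getTable(st, tref, as = "outsider"), "access error")
    setGroupPolicy(st, "other", "public_read")  # raising another group: no effect
    expect_error(getTable(st, tref, as = "outsider"), "access error")
    # unlinked tables are owner-private
    f2 <- tempfile(fileext = ".h5")
    createTable(f2, tableSchema(columnSpec("v", "float64")))
    t2 <- attachTable(st, f2, as = "owner")
    expect_error(getTable(st, t2, as = "outsider"), "access error")
})
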