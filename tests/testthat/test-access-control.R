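# Exhaustive truth table: 4 policy levels x {owner, member, non-member}
# for both read and annotate, straight from the permission model.
permTruth <- data.frame(
    level = rep(c("private", "group_read", "group_read_annotate",
                  "public_read"), each = 3),
    who = rep(c("owner", "member", "outsider"), times = 4),
    read = c(TRUE, FALSE, FALSE,
             TRUE, TRUE, FALSE,
             TRUE, TRUE, FALSE,
             TRUE, TRUE, TRUE),
    annotate = c(TRUE, FALSE, FALSE,
                 TRUE, FALSE, FALSE,
                 TRUE, TRUE, FALSE,
                 TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE)

test_that("read/annotate decisions match the exhaustive truth table", {
    for (lvl in unique(permTruth$level)) {
        fx <- permissionFixture(lvl)
        rows <- permTruth[permTruth$level == lvl, ]
        for (i in seq_len(nrow(rows))) {
            who <- rows$who[i]
            expect_identical(canRead(fx$store, who, fx$obj), rows$read[i],
                             info = paste(lvl, who, "read"))
            expect_identical(canAnnotate(fx$store, who, fx$obj),
                             rows$annotate[i], info = paste(lvl, who, "annotate"))
        }
        # admins bypass everything
        expect_true(canRead(fx$store, "root", fx$obj))
        expect_true(canAnnotate(fx$store, "root", fx$obj))
    }
})

test_that("raising the policy level never revokes an allowed action", {
    ladder <- c("private", "group_read", "group_read_annotate")
    prevRead <- c(owner = FALSE, member = FALSE, outsider = FALSE)
    for (lvl in ladder) {
        fx <- permissionFixture(lvl)
        for (who in names(prevRead)) {
            now <- canRead(fx$store, who, fx$obj)
            expect_true(!prevRead[[who]] || now, info = paste(lvl, who))
            prevRead[[who]] <- now
        }
    }
    # adding public_read keeps all reads allowed
    fx <- permissionFixture("public_read")
    for (who in names(prevRead))
        expect_true(!prevRead[[who]] || canRead(fx$store, who, fx$obj))
})

test_that("ownership reassignment follows the facility-import workflow", {
    st <- newTestStore()
    addPrincipal(st, "manager", "facility", is_admin = FALSE)
    addPrincipal(st, "scientist", "facility")
    p <- createPlate(st, "imported", format = 384, as = "manager")
    expect_false(canRead(st, "scientist", p))     # facility policy is private
    reassignOwner(st, p, "scientist", actor = "manager")
    expect_true(canRead(st, "scientist", p))
    # old owner loses access once no longer owner (private group)
    expect_false(canRead(st, "manager", p))
    expect_error(reassignOwner(st, p, "manager", actor = "manager"),
                 "access error")
    expect_error(reassignOwner(st, p, "nobody", actor = "scientist"),
                 "unknown principal")
    # annotations keep their creators across reassignment
    a <- annotate(st, p, tagAnnotation("qc"), as = "scientist")
    reassignOwner(st, p, "manager", actor = "scientist")
    expect_identical(objectInfo(st, a)$owner, "scientist")
})

test_that("group policies cannot be lowered once objects exist", {
    st <- newTestStore()
    addPrincipal(st, "u", "g")
    setGroupPolicy(st, "g", "group_read_annotate")
    createPlate(st, "p", format = 96, as = "u")
    expect_error(setGroupPolicy(st, "g", "private"), "cannot lower")
    setGroupPolicy(st, "g", "public_read")   # raising stays legal
    expect_true(canRead(st, principal("stranger"), createPlate(st, "q",
                                                               format = 96,
                                                               as = "u")))
})

test_that("a private object is unreachable through every read surface", {
    st <- newTestStore()
    addPrincipal(st, "owner", "lab")
    addPrincipal(st, "outsider", "other")
    p <- createPlate(st, "hidden", format = 96, as = "owner")
    w <- wellAt(st, p, "A1")
    annotate(st, w, mapAnnotation(c("Cell line" = "U2OS")), as = "owner")
    f <- tempfile(fileext = ".h5")
    tab <- createTable(f, tableSchema(columnSpec("well", "well_ref"),
                                      columnSpec("v", "float64")))
    appendRows(tab, list(well = w@oid, v = 1))
    tref <- attachTable(st, f, target = p, as = "owner")
    reindex(st)

    # object record
    expect_error(objectInfo(st, p, as = "outsider"), "access error")
    # annotation listing
    expect_error(getAnnotations(st, w, as = "outsider"), "access error")
    # typed map query filters the target out
    expect_equal(nrow(queryMap(st, "Cell line", as = "outsider")), 0)
    expect_equal(nrow(queryMap(st, "Cell line", as = "owner")), 1)
    # table access (read and backlink both gate through getTable)
    expect_error(getTable(st, tref, as = "outsider"), "access error")
    # search
    expect_equal(nrow(searchStore(st, "U2OS", as = "outsider")), 0)
    expect_gt(nrow(searchStore(st, "U2OS", as = "owner")), 0)
})
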