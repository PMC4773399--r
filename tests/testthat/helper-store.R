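# Shared fixtures and independent oracles. Oracles deliberately avoid the
# code paths they check: brute-force scans, naive sorts, and a separate
# tokenizer implementation.

newTestStore <- function() initStore(tempfile("store"))

# independent tokenizer (regex extraction rather than splitting)
oracleTokens <- function(text) {
    m <- gregexpr("[A-Za-z0-9]+", tolower(paste(text, collapse = " ")))
    unlist(regmatches(tolower(paste(text, collapse = " ")), m))
}

# brute-force row scan of an in-memory column list against condition terms
oracleScan <- function(columns, conds) {
    n <- length(columns[[1L]])
    hits <- integer()
    for (i in seq_len(n)) {
        ok <- TRUE
        for (cond in conds) {
            v <- columns[[cond$column]][i]
            r <- switch(cond$op,
                "==" = v == cond$value, "!=" = v != cond$value,
                "<" = v < cond$value, "<=" = v <= cond$value,
                ">" = v > cond$value, ">=" = v >= cond$value)
            if (is.na(r) || !r) { ok <- FALSE; break }
        }
        if (ok) hits <- c(hits, i - 1L)
    }
    as.double(hits)
}

# build a store holding random map annotations on wells of a small plate;
# returns the store plus a shadow list for linear-scan oracles
randomAnnotatedStore <- function(seed, n_ann = 12, keys = c("Cell line", "Stain"),
                                 values = c("U2OS", "HeLa", "MCF10A")) {
    set.seed(seed)
    st <- newTestStore()
    p <- createPlate(st, "p", format = 96)
    shadow <- list()
    for (i in seq_len(n_ann)) {
        r <- sample(0:7, 1); co <- sample(0:11, 1)
        w <- wellAt(st, p, row = r, column = co)
        npair <- sample(1:3, 1)
        pairs <- data.frame(key = sample(keys, npair, replace = TRUE),
                            value = sample(values, npair, replace = TRUE),
                            unit = NA_character_, stringsAsFactors = FALSE)
        ref <- annotate(st, w, mapAnnotation(pairs))
        shadow[[i]] <- list(target = w, ann = ref, pairs = pairs)
    }
    list(store = st, plate = p, shadow = shadow)
}

# linear scan over the shadow copy, mirroring queryMap's contract
oracleQueryMap <- function(shadow, key, value = NULL) {
    rows <- list()
    for (s in shadow) {
        ok <- s$pairs$key == key
        if (!is.null(value)) ok <- ok & s$pairs$value == value
        if (any(ok))
            rows[[length(rows) + 1L]] <-
                data.frame(target_otype = s$target@otype,
                           target_oid = s$target@oid,
                           annotation_oid = s$ann@oid,
                           stringsAsFactors = FALSE)
    }
    if (!length(rows))
        return(data.frame(target_otype = character(), target_oid = numeric(),
                          annotation_oid = numeric(), stringsAsFactors = FALSE))
    out <- unique(do.call(rbind, rows))
    out <- out[order(out$target_otype, out$target_oid, out$annotation_oid), ,
               drop = FALSE]
    rownames(out) <- NULL
    out
}

# multiset signature of a plate's map annotations in a namespace
annotationMultiset <- function(store, plate, namespace) {
    p <- objectInfo(store, plate)
    sigs <- character()
    for (oid in p$wells[!is.na(p$wells)]) {
        anns <- getAnnotations(store, objectRef("well", oid),
                               namespace = namespace)
        for (a in anns)
            if (is(a, "MapAnnotation"))
                sigs <- c(sigs, paste(a@pairs$key, a@pairs$value, a@pairs$unit,
                                      sep = "\x1f", collapse = "\x1e"))
    }
    sort(sigs)
}

# random bulk-annotation sheet over a 96-well plate
writeRandomSheet <- function(path, seed) {
    set.seed(seed)
    ncol <- sample(2:4, 1)
    keys <- paste0("K", seq_len(ncol))
    units <- sample(c(NA, "s", "nm", "°C"), ncol, replace = TRUE)
    headers <- ifelse(is.na(units), keys, sprintf("%s [%s]", keys, units))
    n <- sample(3:20, 1)
    addr <- sample(as.vector(outer(LETTERS[1:8], 1:12, paste0)), n)
    vals <- matrix(sample(c(letters, 0:9), n * ncol, replace = TRUE), n)
    lines <- c(paste(c("Well", headers), collapse = ","),
               vapply(seq_len(n), function(i)
                   paste(c(addr[i], vals[i, ]), collapse = ","), ""))
    writeLines(lines, path)
    n
}

# store with one private-group owner and assorted other principals
permissionFixture <- function(level) {
    st <- newTestStore()
    addPrincipal(st, "owner", "lab")
    addPrincipal(st, "member", "lab")
    addPrincipal(st, "outsider", "other")
    setGroupPolicy(st, "lab", level)
    obj <- createPlate(st, "p", format = 96, as = "owner")
    list(store = st, obj = obj)
}
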