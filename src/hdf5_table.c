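/* Columnar append-only table store on HDF5.
 *
 * Layout: one group "/table" per file; one 1-D chunked, extensible dataset
 * per column, named by the column; schema held as group attributes
 * ("names", "kinds", "widths", "version") plus a "nrow" row counter that is
 * updated only after all column writes succeed, so a failed append never
 * advances the visible row count.
 *
 * Object time-tracking is disabled everywhere so that identical write
 * sequences produce byte-identical files.
 */

#include <R.h>
#include <Rinternals.h>
#include <hdf5.h>
#include <string.h>
#include <stdint.h>

#define HT_GROUP "table"
#define HT_VERSION "hcstore-table-1"
#define HT_CHUNK 65536

typedef enum { K_INT64, K_FLOAT64, K_BOOL, K_STRING } ht_kind;

static ht_kind kind_code(const char *k)
{
    if (strcmp(k, "float64") == 0) return K_FLOAT64;
    if (strcmp(k, "bool") == 0) return K_BOOL;
    if (strcmp(k, "string") == 0) return K_STRING;
    /* int64 and the *_ref kinds share int64 storage */
    return K_INT64;
}

static void ht_silence(void)
{
    H5Eset_auto2(H5E_DEFAULT, NULL, NULL);
}

static hid_t ht_no_times_pl(hid_t cls)
{
    hid_t pl = H5Pcreate(cls);
    if (pl >= 0) H5Pset_obj_track_times(pl, 0);
    return pl;
}

static void write_str_attr(hid_t loc, const char *name, SEXP vals)
{
    R_xlen_t n = XLENGTH(vals);
    hid_t st = H5Tcopy(H5T_C_S1);
    H5Tset_size(st, H5T_VARIABLE);
    H5Tset_cset(st, H5T_CSET_UTF8);
    hsize_t dims = (hsize_t) n;
    hid_t sp = (n == 1) ? H5Screate(H5S_SCALAR) : H5Screate_simple(1, &dims, NULL);
    hid_t at = H5Acreate2(loc, name, st, sp, H5P_DEFAULT, H5P_DEFAULT);
    const char **buf = (const char **) R_alloc(n, sizeof(char *));
    for (R_xlen_t i = 0; i < n; i++)
        buf[i] = Rf_translateCharUTF8(STRING_ELT(vals, i));
    if (H5Awrite(at, st, buf) < 0) Rf_error("HDF5: failed writing attribute '%s'", name);
    H5Aclose(at); H5Sclose(sp); H5Tclose(st);
}

static SEXP read_str_attr(hid_t loc, const char *name)
{
    hid_t at = H5Aopen(loc, name, H5P_DEFAULT);
    if (at < 0) Rf_error("HDF5: missing attribute '%s'", name);
    hid_t sp = H5Aget_space(at);
    hsize_t n = 1;
    if (H5Sget_simple_extent_ndims(sp) == 1)
        H5Sget_simple_extent_dims(sp, &n, NULL);
    hid_t st = H5Tcopy(H5T_C_S1);
    H5Tset_size(st, H5T_VARIABLE);
    H5Tset_cset(st, H5T_CSET_UTF8);
    char **buf = (char **) R_alloc(n, sizeof(char *));
    if (H5Aread(at, st, buf) < 0) Rf_error("HDF5: failed reading attribute '%s'", name);
    SEXP out = PROTECT(Rf_allocVector(STRSXP, (R_xlen_t) n));
    for (hsize_t i = 0; i < n; i++)
        SET_STRING_ELT(out, (R_xlen_t) i, Rf_mkCharCE(buf[i], CE_UTF8));
    H5Dvlen_reclaim(st, sp, H5P_DEFAULT, buf);
    H5Tclose(st); H5Sclose(sp); H5Aclose(at);
    UNPROTECT(1);
    return out;
}

static void write_nrow(hid_t grp, long long nrow, int create)
{
    hid_t at;
    if (create) {
        hid_t sp = H5Screate(H5S_SCALAR);
        at = H5Acreate2(grp, "nrow", H5T_NATIVE_LLONG, sp, H5P_DEFAULT, H5P_DEFAULT);
        H5Sclose(sp);
    } else {
        at = H5Aopen(grp, "nrow", H5P_DEFAULT);
    }
    if (at < 0 || H5Awrite(at, H5T_NATIVE_LLONG, &nrow) < 0)
        Rf_error("HDF5: failed writing row count");
    H5Aclose(at);
}

static long long read_nrow(hid_t grp)
{
    long long nrow = 0;
    hid_t at = H5Aopen(grp, "nrow", H5P_DEFAULT);
    if (at < 0 || H5Aread(at, H5T_NATIVE_LLONG, &nrow) < 0)
        Rf_error("HDF5: failed reading row count");
    H5Aclose(at);
    return nrow;
}

static hid_t mem_type_for(ht_kind k, int width)
{
    hid_t t;
    switch (k) {
    case K_FLOAT64: return H5Tcopy(H5T_NATIVE_DOUBLE);
    case K_BOOL:    return H5Tcopy(H5T_NATIVE_SCHAR);
    case K_STRING:
        t = H5Tcopy(H5T_C_S1);
        H5Tset_size(t, (size_t) width);
        H5Tset_strpad(t, H5T_STR_NULLPAD);
        H5Tset_cset(t, H5T_CSET_UTF8);
        return t;
    default:        return H5Tcopy(H5T_NATIVE_LLONG);
    }
}

SEXP C_ht_create(SEXP path, SEXP names, SEXP kinds, SEXP widths)
{
    ht_silence();
    const char *fn = Rf_translateChar(STRING_ELT(path, 0));
    int ncol = LENGTH(names);

    hid_t fcpl = ht_no_times_pl(H5P_FILE_CREATE);
    hid_t fid = H5Fcreate(fn, H5F_ACC_EXCL, fcpl, H5P_DEFAULT);
    H5Pclose(fcpl);
    if (fid < 0) Rf_error("cannot create table file '%s' (exists or unwritable)", fn);

    hid_t gcpl = ht_no_times_pl(H5P_GROUP_CREATE);
    hid_t grp = H5Gcreate2(fid, HT_GROUP, H5P_DEFAULT, gcpl, H5P_DEFAULT);
    H5Pclose(gcpl);
    if (grp < 0) { H5Fclose(fid); Rf_error("HDF5: group creation failed"); }

    write_str_attr(grp, "names", names);
    write_str_attr(grp, "kinds", kinds);
    {
        hsize_t d = (hsize_t) ncol;
        hid_t sp = H5Screate_simple(1, &d, NULL);
        hid_t at = H5Acreate2(grp, "widths", H5T_NATIVE_INT, sp, H5P_DEFAULT, H5P_DEFAULT);
        H5Awrite(at, H5T_NATIVE_INT, INTEGER(widths));
        H5Aclose(at); H5Sclose(sp);
    }
    write_str_attr(grp, "version", Rf_mkString(HT_VERSION));
    write_nrow(grp, 0, 1);

    for (int j = 0; j < ncol; j++) {
        ht_kind k = kind_code(CHAR(STRING_ELT(kinds, j)));
        hid_t ft = mem_type_for(k, INTEGER(widths)[j]);
        hsize_t dims = 0, maxdims = H5S_UNLIMITED, chunk = HT_CHUNK;
        hid_t sp = H5Screate_simple(1, &dims, &maxdims);
        hid_t dcpl = ht_no_times_pl(H5P_DATASET_CREATE);
        H5Pset_chunk(dcpl, 1, &chunk);
        hid_t ds = H5Dcreate2(grp, Rf_translateCharUTF8(STRING_ELT(names, j)),
                              ft, sp, H5P_DEFAULT, dcpl, H5P_DEFAULT);
        if (ds < 0) Rf_error("HDF5: dataset creation failed for column %d", j + 1);
        H5Dclose(ds); H5Pclose(dcpl); H5Sclose(sp); H5Tclose(ft);
    }
    H5Gclose(grp);
    H5Fclose(fid);
    return R_NilValue;
}

static hid_t open_file(const char *fn, unsigned flags)
{
    hid_t fid = H5Fopen(fn, flags, H5P_DEFAULT);
    if (fid < 0) Rf_error("cannot open table file '%s'", fn);
    return fid;
}

SEXP C_ht_info(SEXP path)
{
    ht_silence();
    hid_t fid = open_file(Rf_translateChar(STRING_ELT(path, 0)), H5F_ACC_RDONLY);
    hid_t grp = H5Gopen2(fid, HT_GROUP, H5P_DEFAULT);
    if (grp < 0) { H5Fclose(fid); Rf_error("no table group in file"); }

    SEXP names = PROTECT(read_str_attr(grp, "names"));
    SEXP kinds = PROTECT(read_str_attr(grp, "kinds"));
    int ncol = LENGTH(names);
    SEXP widths = PROTECT(Rf_allocVector(INTSXP, ncol));
    {
        hid_t at = H5Aopen(grp, "widths", H5P_DEFAULT);
        if (at < 0 || H5Aread(at, H5T_NATIVE_INT, INTEGER(widths)) < 0)
            Rf_error("HDF5: failed reading widths");
        H5Aclose(at);
    }
    SEXP version = PROTECT(read_str_attr(grp, "version"));
    long long nrow = read_nrow(grp);
    H5Gclose(grp); H5Fclose(fid);

    SEXP out = PROTECT(Rf_allocVector(VECSXP, 5));
    SEXP nm = PROTECT(Rf_allocVector(STRSXP, 5));
    SET_VECTOR_ELT(out, 0, names);    SET_STRING_ELT(nm, 0, Rf_mkChar("names"));
    SET_VECTOR_ELT(out, 1, kinds);    SET_STRING_ELT(nm, 1, Rf_mkChar("kinds"));
    SET_VECTOR_ELT(out, 2, widths);   SET_STRING_ELT(nm, 2, Rf_mkChar("widths"));
    SET_VECTOR_ELT(out, 3, Rf_ScalarReal((double) nrow)); SET_STRING_ELT(nm, 3, Rf_mkChar("nrow"));
    SET_VECTOR_ELT(out, 4, version);  SET_STRING_ELT(nm, 4, Rf_mkChar("version"));
    Rf_setAttrib(out, R_NamesSymbol, nm);
    UNPROTECT(6);
    return out;
}

/* block: list aligned with schema order; int64-like columns arrive as REALSXP
 * of whole numbers, float64 as REALSXP, bool as LGLSXP, string as STRSXP.
 * Validation (types, lengths, widths, finiteness rules) happens in R. */
SEXP C_ht_append(SEXP path, SEXP kinds, SEXP widths, SEXP block)
{
    ht_silence();
    int ncol = LENGTH(kinds);
    R_xlen_t n = XLENGTH(VECTOR_ELT(block, 0));

    hid_t fid = open_file(Rf_translateChar(STRING_ELT(path, 0)), H5F_ACC_RDWR);
    hid_t grp = H5Gopen2(fid, HT_GROUP, H5P_DEFAULT);
    if (grp < 0) { H5Fclose(fid); Rf_error("no table group in file"); }
    long long nrow = read_nrow(grp);
    SEXP names = PROTECT(read_str_attr(grp, "names"));

    for (int j = 0; j < ncol; j++) {
        ht_kind k = kind_code(CHAR(STRING_ELT(kinds, j)));
        int w = INTEGER(widths)[j];
        hid_t ds = H5Dopen2(grp, Rf_translateCharUTF8(STRING_ELT(names, j)), H5P_DEFAULT);
        hsize_t newsize = (hsize_t)(nrow + n);
        if (H5Dset_extent(ds, &newsize) < 0) Rf_error("HDF5: extent failed");
        hid_t fsp = H5Dget_space(ds);
        hsize_t off = (hsize_t) nrow, cnt = (hsize_t) n;
        H5Sselect_hyperslab(fsp, H5S_SELECT_SET, &off, NULL, &cnt, NULL);
        hid_t msp = H5Screate_simple(1, &cnt, NULL);
        hid_t mt = mem_type_for(k, w);
        SEXP col = VECTOR_ELT(block, j);
        const void *buf = NULL;
        herr_t st = -1;
        if (k == K_INT64) {
            long long *b = (long long *) R_alloc(n, sizeof(long long));
            const double *x = REAL(col);
            for (R_xlen_t i = 0; i < n; i++) b[i] = (long long) x[i];
            buf = b;
        } else if (k == K_FLOAT64) {
            buf = REAL(col);
        } else if (k == K_BOOL) {
            signed char *b = (signed char *) R_alloc(n, 1);
            const int *x = LOGICAL(col);
            for (R_xlen_t i = 0; i < n; i++) b[i] = (signed char)(x[i] != 0);
            buf = b;
        } else {
            char *b = (char *) R_alloc(n, (size_t) w);
            memset(b, 0, (size_t) n * (size_t) w);
            for (R_xlen_t i = 0; i < n; i++) {
                const char *s = Rf_translateCharUTF8(STRING_ELT(col, i));
                size_t len = strlen(s);
                if (len > (size_t) w) len = (size_t) w;
                memcpy(b + (size_t) i * (size_t) w, s, len);
            }
            buf = b;
        }
        st = H5Dwrite(ds, mt, msp, fsp, H5P_DEFAULT, buf);
        H5Tclose(mt); H5Sclose(msp); H5Sclose(fsp); H5Dclose(ds);
        if (st < 0) Rf_error("HDF5: write failed for column %d", j + 1);
    }
    write_nrow(grp, nrow + n, 0);
    H5Gclose(grp);
    H5Fclose(fid);
    UNPROTECT(1);
    return Rf_ScalarReal((double) nrow);
}

/* cols: 1-based integer indices into the schema; [start, stop) half-open,
 * 0-based row range (validated in R against the nrow attribute). */
SEXP C_ht_read(SEXP path, SEXP names, SEXP kinds, SEXP widths, SEXP cols,
               SEXP start_, SEXP stop_)
{
    ht_silence();
    R_xlen_t nsel = XLENGTH(cols);
    long long start = (long long) REAL(start_)[0];
    long long stop = (long long) REAL(stop_)[0];
    R_xlen_t n = (R_xlen_t)(stop - start);

    hid_t fid = open_file(Rf_translateChar(STRING_ELT(path, 0)), H5F_ACC_RDONLY);
    hid_t grp = H5Gopen2(fid, HT_GROUP, H5P_DEFAULT);
    if (grp < 0) { H5Fclose(fid); Rf_error("no table group in file"); }

    SEXP out = PROTECT(Rf_allocVector(VECSXP, nsel));
    SEXP outnm = PROTECT(Rf_allocVector(STRSXP, nsel));
    for (R_xlen_t s = 0; s < nsel; s++) {
        int j = INTEGER(cols)[s] - 1;
        ht_kind k = kind_code(CHAR(STRING_ELT(kinds, j)));
        int w = INTEGER(widths)[j];
        SET_STRING_ELT(outnm, s, STRING_ELT(names, j));
        hid_t ds = H5Dopen2(grp, Rf_translateCharUTF8(STRING_ELT(names, j)), H5P_DEFAULT);
        if (ds < 0) Rf_error("HDF5: missing column dataset");
        hid_t fsp = H5Dget_space(ds);
        hsize_t off = (hsize_t) start, cnt = (hsize_t) n;
        H5Sselect_hyperslab(fsp, H5S_SELECT_SET, &off, NULL, &cnt, NULL);
        hid_t msp = H5Screate_simple(1, &cnt, NULL);
        hid_t mt = mem_type_for(k, w);
        SEXP col;
        herr_t st;
        if (k == K_FLOAT64) {
            col = PROTECT(Rf_allocVector(REALSXP, n));
            st = H5Dread(ds, mt, msp, fsp, H5P_DEFAULT, REAL(col));
        } else if (k == K_INT64) {
            long long *b = (long long *) R_alloc(n, sizeof(long long));
            st = H5Dread(ds, mt, msp, fsp, H5P_DEFAULT, b);
            col = PROTECT(Rf_allocVector(REALSXP, n));
            for (R_xlen_t i = 0; i < n; i++) REAL(col)[i] = (double) b[i];
        } else if (k == K_BOOL) {
            signed char *b = (signed char *) R_alloc(n, 1);
            st = H5Dread(ds, mt, msp, fsp, H5P_DEFAULT, b);
            col = PROTECT(Rf_allocVector(LGLSXP, n));
            for (R_xlen_t i = 0; i < n; i++) LOGICAL(col)[i] = (int) b[i];
        } else {
            char *b = (char *) R_alloc(n, (size_t) w);
            st = H5Dread(ds, mt, msp, fsp, H5P_DEFAULT, b);
            col = PROTECT(Rf_allocVector(STRSXP, n));
            for (R_xlen_t i = 0; i < n; i++) {
                const char *p = b + (size_t) i * (size_t) w;
                size_t len = 0;
                while (len < (size_t) w && p[len] != '\0') len++;
                SET_STRING_ELT(col, i, Rf_mkCharLenCE(p, (int) len, CE_UTF8));
            }
        }
        H5Tclose(mt); H5Sclose(msp); H5Sclose(fsp); H5Dclose(ds);
        if (st < 0) Rf_error("HDF5: read failed for column %d", j + 1);
        SET_VECTOR_ELT(out, s, col);
        UNPROTECT(1);
    }
    H5Gclose(grp); H5Fclose(fid);
    Rf_setAttrib(out, R_NamesSymbol, outnm);
    UNPROTECT(2);
    return out;
}
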