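#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

SEXP C_ht_create(SEXP, SEXP, SEXP, SEXP);
SEXP C_ht_info(SEXP);
SEXP C_ht_append(SEXP, SEXP, SEXP, SEXP);
SEXP C_ht_read(SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP);

static const R_CallMethodDef callMethods[] = {
    {"C_ht_create", (DL_FUNC) &C_ht_create, 4},
    {"C_ht_info",   (DL_FUNC) &C_ht_info,   1},
    {"C_ht_append", (DL_FUNC) &C_ht_append, 4},
    {"C_ht_read",   (DL_FUNC) &C_ht_read,   7},
    {NULL, NULL, 0}
};

void R_init_hcstore(DllInfo *info)
{
    R_registerRoutines(info, NULL, callMethods, NULL, NULL);
    R_useDynamicSymbols(info, FALSE);
    R_forceSymbols(info, TRUE);
}
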