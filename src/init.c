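#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

SEXP sb_sos_filter(SEXP x_, SEXP b_, SEXP a_, SEXP nsec_);

static const R_CallMethodDef CallEntries[] = {
    {"sb_sos_filter", (DL_FUNC) &sb_sos_filter, 4},
    {NULL, NULL, 0}
};

void R_init_spikebench(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
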