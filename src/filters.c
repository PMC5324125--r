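/* Direct-form II transposed biquad cascade.
 *
 * x: numeric vector; b, a: 3 x nsec coefficient matrices (column-major,
 * a[0] assumed 1 per section). Returns the filtered vector. Zero initial
 * state: callers handle edge transients by padding.
 */
#include <R.h>
#include <Rinternals.h>
#include <string.h>

SEXP sb_sos_filter(SEXP x_, SEXP b_, SEXP a_, SEXP nsec_)
{
    const R_xlen_t n = XLENGTH(x_);
    const int nsec = INTEGER(nsec_)[0];
    const double *b = REAL(b_);
    const double *a = REAL(a_);

    SEXP y_ = PROTECT(allocVector(REALSXP, n));
    double *y = REAL(y_);
    memcpy(y, REAL(x_), n * sizeof(double));

    for (int s = 0; s < nsec; s++) {
        const double b0 = b[3 * s], b1 = b[3 * s + 1], b2 = b[3 * s + 2];
        const double a1 = a[3 * s + 1], a2 = a[3 * s + 2];
        double z1 = 0.0, z2 = 0.0;
        for (R_xlen_t i = 0; i < n; i++) {
            const double xi = y[i];
            const double yi = b0 * xi + z1;
            z1 = b1 * xi - a1 * yi + z2;
            z2 = b2 * xi - a2 * yi;
            y[i] = yi;
        }
    }
    UNPROTECT(1);
    return y_;
}
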