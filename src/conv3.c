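/* Fused 3x3 convolution kernels for the CNN engine.
 *
 * Activations are (B*H*W) x C column-major matrices (pixels column-major
 * within each image, images stacked).  A 3x3 same-padding convolution is
 * nine shifted matrix products: Y = sum_k shift_k(X) %*% W_k.  Each shift
 * is (almost) a constant row offset o_k of the activation matrix, so the
 * product is computed with dgemm on pointer-offset views, tiled over rows
 * so the output tile stays cache-resident across the nine accumulations.
 * Rows whose shifted read wraps across an image column or image boundary
 * (precomputed per geometry) are corrected afterwards by subtracting the
 * wrong rank-1 contribution; the true contribution there is zero.
 *
 * Weights are stored (9*Cin) x Cout with shift-major blocks: rows
 * [k*Cin, (k+1)*Cin) hold W_k.
 */
#define USE_FC_LEN_T
#include <R.h>
#include <Rinternals.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
# define FCONE
#endif

#define TILE 8192

/* Y = conv(X, W) (+ bias); offs/lo/hi are the 9 row offsets and valid
 * global ranges, bad is a list of 9 integer vectors of rows to correct. */
SEXP nq_conv3_fwd(SEXP X, SEXP W, SEXP offs, SEXP lo, SEXP hi, SEXP bad,
                  SEXP bias)
{
    const int N = Rf_nrows(X);
    const int Cin = Rf_ncols(X);
    const int Cout = Rf_ncols(W);
    const int ldw = Rf_nrows(W);      /* 9*Cin */
    const double *x = REAL(X), *w = REAL(W);
    const int *o = INTEGER(offs), *vlo = INTEGER(lo), *vhi = INTEGER(hi);
    const double one = 1.0;

    SEXP Ys = PROTECT(Rf_allocMatrix(REALSXP, N, Cout));
    double *y = REAL(Ys);

    if (bias == R_NilValue)
        for (R_xlen_t i = 0; i < (R_xlen_t) N * Cout; i++) y[i] = 0.0;
    else {
        const double *b = REAL(bias);
        for (int c = 0; c < Cout; c++) {
            double *yc = y + (size_t) c * N;
            for (int r = 0; r < N; r++) yc[r] = b[c];
        }
    }

    for (int t0 = 1; t0 <= N; t0 += TILE) {
        int t1 = t0 + TILE - 1; if (t1 > N) t1 = N;
        for (int k = 0; k < 9; k++) {
            int a = t0 > vlo[k] ? t0 : vlo[k];
            int bnd = t1 < vhi[k] ? t1 : vhi[k];
            int m = bnd - a + 1;
            if (m <= 0) continue;
            F77_CALL(dgemm)("N", "N", &m, (int *) &Cout, (int *) &Cin, &one,
                            x + (a - 1 + o[k]), (int *) &N,
                            w + (size_t) k * Cin, (int *) &ldw, &one,
                            y + (a - 1), (int *) &N FCONE FCONE);
        }
    }

    for (int k = 0; k < 9; k++) {
        SEXP bk = VECTOR_ELT(bad, k);
        const int *br = INTEGER(bk);
        const int nb = LENGTH(bk);
        const double *wk = w + (size_t) k * Cin;
        for (int i = 0; i < nb; i++) {
            const double *xr = x + (br[i] - 1 + o[k]);
            double *yr = y + (br[i] - 1);
            for (int c = 0; c < Cout; c++) {
                double acc = 0.0;
                const double *wc = wk + (size_t) c * ldw;
                for (int ci = 0; ci < Cin; ci++)
                    acc += xr[(size_t) ci * N] * wc[ci];
                yr[(size_t) c * N] -= acc;
            }
        }
    }
    UNPROTECT(1);
    return Ys;
}

/* dW = sum over rows of shift_k(X)^T dY, same shift bookkeeping. */
SEXP nq_conv3_dw(SEXP X, SEXP dY, SEXP offs, SEXP lo, SEXP hi, SEXP bad)
{
    const int N = Rf_nrows(X);
    const int Cin = Rf_ncols(X);
    const int Cout = Rf_ncols(dY);
    const int ldw = 9 * Cin;
    const double *x = REAL(X), *dy = REAL(dY);
    const int *o = INTEGER(offs), *vlo = INTEGER(lo), *vhi = INTEGER(hi);
    const double one = 1.0;

    SEXP dWs = PROTECT(Rf_allocMatrix(REALSXP, ldw, Cout));
    double *dw = REAL(dWs);
    for (R_xlen_t i = 0; i < (R_xlen_t) ldw * Cout; i++) dw[i] = 0.0;

    for (int t0 = 1; t0 <= N; t0 += TILE) {
        int t1 = t0 + TILE - 1; if (t1 > N) t1 = N;
        for (int k = 0; k < 9; k++) {
            int a = t0 > vlo[k] ? t0 : vlo[k];
            int bnd = t1 < vhi[k] ? t1 : vhi[k];
            int m = bnd - a + 1;
            if (m <= 0) continue;
            F77_CALL(dgemm)("T", "N", (int *) &Cin, (int *) &Cout, &m, &one,
                            x + (a - 1 + o[k]), (int *) &N,
                            dy + (a - 1), (int *) &N, &one,
                            dw + (size_t) k * Cin, (int *) &ldw FCONE FCONE);
        }
    }

    for (int k = 0; k < 9; k++) {
        SEXP bk = VECTOR_ELT(bad, k);
        const int *br = INTEGER(bk);
        const int nb = LENGTH(bk);
        double *dwk = dw + (size_t) k * Cin;
        for (int i = 0; i < nb; i++) {
            const double *xr = x + (br[i] - 1 + o[k]);
            const double *dyr = dy + (br[i] - 1);
            for (int c = 0; c < Cout; c++) {
                double g = dyr[(size_t) c * N];
                double *dwc = dwk + (size_t) c * ldw;
                for (int ci = 0; ci < Cin; ci++)
                    dwc[ci] -= xr[(size_t) ci * N] * g;
            }
        }
    }
    UNPROTECT(1);
    return dWs;
}

static const R_CallMethodDef CallEntries[] = {
    {"nq_conv3_fwd", (DL_FUNC) &nq_conv3_fwd, 7},
    {"nq_conv3_dw",  (DL_FUNC) &nq_conv3_dw, 6},
    {NULL, NULL, 0}
};

void R_init_neuroqpi(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
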