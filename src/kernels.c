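#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

/* Gather the im2col matrix for a batched valid convolution.
 *
 * A:   double matrix (n_rows_A x c_in)
 * idx: integer vector, length n_out_rows * k3, 1-based row indices into A
 *      (tap-major: idx[i + n_out_rows * t] is the input row of tap t for
 *      output row i)
 * Returns a double matrix (n_out_rows x (k3 * c_in)) whose element
 * (i, t + k3 * ch) equals A[idx[i + n_out_rows * t], ch], i.e. exactly
 * `{B <- A[idx, ]; dim(B) <- c(n_out_rows, k3 * c_in); B}`.
 */
SEXP C_gather_cols(SEXP A, SEXP idx, SEXP n_out_rows, SEXP k3)
{
    const double *a = REAL(A);
    const int *ix = INTEGER(idx);
    const R_xlen_t nA = Rf_nrows(A);
    const R_xlen_t c_in = Rf_ncols(A);
    const R_xlen_t nrw = (R_xlen_t) INTEGER(n_out_rows)[0];
    const R_xlen_t nk = (R_xlen_t) INTEGER(k3)[0];
    const R_xlen_t L = nrw * nk;
    if (XLENGTH(idx) != L)
        Rf_error("index length does not match n_out_rows * k3");
    SEXP out = PROTECT(Rf_allocMatrix(REALSXP, (int) nrw, (int) (nk * c_in)));
    double *o = REAL(out);
    for (R_xlen_t ch = 0; ch < c_in; ch++) {
        const double *acol = a + ch * nA;
        double *ocol = o + ch * L;   /* k3 consecutive output columns */
        for (R_xlen_t l = 0; l < L; l++) {
            ocol[l] = acol[ix[l] - 1];
        }
    }
    UNPROTECT(1);
    return out;
}

/* Scatter-accumulate the convolution input gradient.
 *
 * Equivalent to, for j in 1:k3 (in that order):
 *   dA[idx[, j], ] <- dA[idx[, j], ] + dcols[, j + k3 * (0:(c_in-1))]
 * The row map is injective within a tap, so each target element receives
 * exactly one contribution per tap; taps are applied in index order.
 *
 * dA:    double matrix (n_rows_A x c_in), modified in place (freshly
 *        allocated by the caller, never shared)
 * idx:   integer vector length nrw * k3, as in C_gather_cols
 * dcols: double matrix (nrw x (k3 * c_in))
 */
SEXP C_scatter_add(SEXP dA, SEXP idx, SEXP dcols, SEXP k3)
{
    double *da = REAL(dA);
    const int *ix = INTEGER(idx);
    const double *dc = REAL(dcols);
    const R_xlen_t nA = Rf_nrows(dA);
    const R_xlen_t c_in = Rf_ncols(dA);
    const R_xlen_t nrw = Rf_nrows(dcols);
    const R_xlen_t nk = (R_xlen_t) INTEGER(k3)[0];
    if (XLENGTH(idx) != nrw * nk)
        Rf_error("index length does not match dcols rows * k3");
    if (Rf_ncols(dcols) != nk * c_in)
        Rf_error("dcols columns do not match k3 * c_in");
    for (R_xlen_t j = 0; j < nk; j++) {
        const int *ixj = ix + j * nrw;
        for (R_xlen_t ch = 0; ch < c_in; ch++) {
            const double *dcol = dc + (j + nk * ch) * nrw;
            double *acol = da + ch * nA;
            for (R_xlen_t i = 0; i < nrw; i++) {
                acol[ixj[i] - 1] += dcol[i];
            }
        }
    }
    return dA;
}

/* Fused mLDRW model evaluation (value and, optionally, Jacobian).
 *
 * Replicates, with identical operation ordering per element, the R
 * expressions
 *   s  <- outer(-t0, t, `+`); pos <- s > 0; s[!pos] <- 1
 *   g  <- sqrt(kappa / (2 * pi * s)) * exp(-kappa * (s - mu)^2 / (2 * s))
 *   f  <- auc * g                                  (g zeroed where !pos)
 *   dk <- f * (1 / (2 * kappa) - (s - mu)^2 / (2 * s))
 *   dm <- f * (kappa * (s - mu) / s)
 *   dt0 <- -f * (-1 / (2 * s) - kappa * (s^2 - mu^2) / (2 * s^2))
 *   da <- g
 * theta: double matrix (n x 4), columns kappa, mu, t0, auc
 * t:     double vector (m)
 * Returns list(f, support, J = list(dk, dm, dt0, da)) or list(f, support).
 */
SEXP C_mldrw_eval(SEXP theta, SEXP t, SEXP jacobian)
{
    const double *th = REAL(theta);
    const double *tt = REAL(t);
    const R_xlen_t n = Rf_nrows(theta);
    const R_xlen_t m = XLENGTH(t);
    const int jac = Rf_asLogical(jacobian);
    const double twopi = 2 * M_PI;

    SEXP f = PROTECT(Rf_allocMatrix(REALSXP, (int) n, (int) m));
    SEXP sup = PROTECT(Rf_allocMatrix(LGLSXP, (int) n, (int) m));
    double *pf = REAL(f);
    int *ps = LOGICAL(sup);
    double *pdk = NULL, *pdm = NULL, *pdt = NULL, *pda = NULL;
    SEXP dk = R_NilValue, dm = R_NilValue, dt0 = R_NilValue, da = R_NilValue;
    int nprot = 2;
    if (jac) {
        dk = PROTECT(Rf_allocMatrix(REALSXP, (int) n, (int) m));
        dm = PROTECT(Rf_allocMatrix(REALSXP, (int) n, (int) m));
        dt0 = PROTECT(Rf_allocMatrix(REALSXP, (int) n, (int) m));
        da = PROTECT(Rf_allocMatrix(REALSXP, (int) n, (int) m));
        nprot += 4;
        pdk = REAL(dk); pdm = REAL(dm); pdt = REAL(dt0); pda = REAL(da);
    }

    for (R_xlen_t j = 0; j < m; j++) {
        const double tj = tt[j];
        const R_xlen_t off = j * n;
        for (R_xlen_t i = 0; i < n; i++) {
            const double kappa = th[i];
            const double mu = th[i + n];
            const double t0v = th[i + 2 * n];
            const double aucv = th[i + 3 * n];
            double s = (-t0v) + tj;
            const int pos = s > 0;
            if (!pos) s = 1.0;
            const double smu = s - mu;
            double g = sqrt(kappa / (twopi * s)) *
                exp(-(kappa * (smu * smu)) / (2 * s));
            if (!pos) g = 0.0;
            const double fv = aucv * g;
            pf[off + i] = fv;
            ps[off + i] = pos;
            if (jac) {
                if (pos) {
                    pdk[off + i] = fv * (1 / (2 * kappa) -
                                         (smu * smu) / (2 * s));
                    pdm[off + i] = fv * (kappa * smu / s);
                    const double dfds = fv * (-(1 / (2 * s)) -
                        (kappa * (s * s - mu * mu)) / (2 * (s * s)));
                    pdt[off + i] = -dfds;
                    pda[off + i] = g;
                } else {
                    pdk[off + i] = 0.0;
                    pdm[off + i] = 0.0;
                    pdt[off + i] = 0.0;
                    pda[off + i] = 0.0;
                }
            }
        }
    }

    SEXP out;
    if (jac) {
        SEXP J = PROTECT(Rf_allocVector(VECSXP, 4));
        SET_VECTOR_ELT(J, 0, dk);
        SET_VECTOR_ELT(J, 1, dm);
        SET_VECTOR_ELT(J, 2, dt0);
        SET_VECTOR_ELT(J, 3, da);
        out = PROTECT(Rf_allocVector(VECSXP, 3));
        SET_VECTOR_ELT(out, 0, f);
        SET_VECTOR_ELT(out, 1, sup);
        SET_VECTOR_ELT(out, 2, J);
        SEXP nm = PROTECT(Rf_allocVector(STRSXP, 3));
        SET_STRING_ELT(nm, 0, Rf_mkChar("f"));
        SET_STRING_ELT(nm, 1, Rf_mkChar("support"));
        SET_STRING_ELT(nm, 2, Rf_mkChar("J"));
        Rf_setAttrib(out, R_NamesSymbol, nm);
        nprot += 3;
    } else {
        out = PROTECT(Rf_allocVector(VECSXP, 2));
        SET_VECTOR_ELT(out, 0, f);
        SET_VECTOR_ELT(out, 1, sup);
        SEXP nm = PROTECT(Rf_allocVector(STRSXP, 2));
        SET_STRING_ELT(nm, 0, Rf_mkChar("f"));
        SET_STRING_ELT(nm, 1, Rf_mkChar("support"));
        Rf_setAttrib(out, R_NamesSymbol, nm);
        nprot += 2;
    }
    UNPROTECT(nprot);
    return out;
}

/* Fused normal-equation reductions for the mLDRW LM step.
 *
 * J: list of 4 double matrices (n x m); r: double matrix (n x m).
 * Computes, with the same long-double column-ascending accumulation order
 * as R's rowSums,
 *   K[[p]] = rowSums(J[[a]] * J[[b]])   for (a, b) in the fixed order
 *            (1,1),(2,1),(3,1),(4,1),(2,2),(3,2),(4,2),(3,3),(4,3),(4,4)
 *   b      = cbind(rowSums(J[[1]]*r), ..., rowSums(J[[4]]*r))
 * Returns list(K = list of 10 vectors, b = n x 4 matrix).
 */
SEXP C_mldrw_normal(SEXP J, SEXP r)
{
    const double *j1 = REAL(VECTOR_ELT(J, 0));
    const double *j2 = REAL(VECTOR_ELT(J, 1));
    const double *j3 = REAL(VECTOR_ELT(J, 2));
    const double *j4 = REAL(VECTOR_ELT(J, 3));
    const double *rr = REAL(r);
    const R_xlen_t n = Rf_nrows(r);
    const R_xlen_t m = Rf_ncols(r);
    const double *jm[4] = {j1, j2, j3, j4};
    static const int pa[10] = {0, 1, 2, 3, 1, 2, 3, 2, 3, 3};
    static const int pb[10] = {0, 0, 0, 0, 1, 1, 1, 2, 2, 3};

    SEXP K = PROTECT(Rf_allocVector(VECSXP, 10));
    double *pk[10];
    for (int p = 0; p < 10; p++) {
        SEXP v = Rf_allocVector(REALSXP, n);
        SET_VECTOR_ELT(K, p, v);
        pk[p] = REAL(v);
    }
    SEXP B = PROTECT(Rf_allocMatrix(REALSXP, (int) n, 4));
    double *bb = REAL(B);
    long double *acc = (long double *) R_alloc((size_t) n, sizeof(long double));

    for (int p = 0; p < 10; p++) {
        const double *xa = jm[pa[p]];
        const double *xb = jm[pb[p]];
        for (R_xlen_t i = 0; i < n; i++) acc[i] = 0.0L;
        for (R_xlen_t j = 0; j < m; j++) {
            const double *ca = xa + j * n;
            const double *cb = xb + j * n;
            for (R_xlen_t i = 0; i < n; i++)
                acc[i] += (long double) (ca[i] * cb[i]);
        }
        double *out = pk[p];
        for (R_xlen_t i = 0; i < n; i++) out[i] = (double) acc[i];
    }
    for (int p = 0; p < 4; p++) {
        const double *xa = jm[p];
        for (R_xlen_t i = 0; i < n; i++) acc[i] = 0.0L;
        for (R_xlen_t j = 0; j < m; j++) {
            const double *ca = xa + j * n;
            const double *cr = rr + j * n;
            for (R_xlen_t i = 0; i < n; i++)
                acc[i] += (long double) (ca[i] * cr[i]);
        }
        double *out = bb + p * n;
        for (R_xlen_t i = 0; i < n; i++) out[i] = (double) acc[i];
    }

    SEXP out = PROTECT(Rf_allocVector(VECSXP, 2));
    SET_VECTOR_ELT(out, 0, K);
    SET_VECTOR_ELT(out, 1, B);
    SEXP nm = PROTECT(Rf_allocVector(STRSXP, 2));
    SET_STRING_ELT(nm, 0, Rf_mkChar("K"));
    SET_STRING_ELT(nm, 1, Rf_mkChar("b"));
    Rf_setAttrib(out, R_NamesSymbol, nm);
    UNPROTECT(4);
    return out;
}

static const R_CallMethodDef call_entries[] = {
    {"C_gather_cols", (DL_FUNC) &C_gather_cols, 4},
    {"C_scatter_add", (DL_FUNC) &C_scatter_add, 4},
    {"C_mldrw_eval",  (DL_FUNC) &C_mldrw_eval,  3},
    {"C_mldrw_normal", (DL_FUNC) &C_mldrw_normal, 2},
    {NULL, NULL, 0}
};

void R_init_mpuscad(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, call_entries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
    R_forceSymbols(dll, TRUE);
}
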