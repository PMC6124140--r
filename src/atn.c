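/* Allometric trophic network right-hand side, callable both as a
 * deSolve compiled model (atn_initmod / atn_derivs / atn_event) and
 * directly from R via .Call (atn_eval_call).
 *
 * Parameter vector layout (doubles), padded to ATN_MAXPAR on the R side:
 *   [0] n        number of guilds
 *   [1] K        shared producer carrying capacity
 *   [2] eps      biomass floor used by the daily clamp event
 *   [3] nfish    number of fish-stage guilds
 *   [4 .. 4+8n)  per-guild blocks: isprod, r, x, y, B0, q, d, h
 *   [.. +n*n)    W  diet preference, column-major, W[i + n*j] = omega(consumer i, prey j)
 *   [.. +n*n)    E  assimilation efficiency, same layout (1 where no link)
 *   [.. +nfish)  fish guild indices (1-based)
 *
 * State vector for the solver: [B (n), P (nfish), C (nfish)] where
 * dP_i = x_i B_i (y_i sum_j F_ij - 1)  (net production of fish stages)
 * dC_i = h_i B_i                        (catch accumulation)
 */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

#define ATN_MAXPAR 25000
#define ATN_MAXN   100

static double parms[ATN_MAXPAR];

void atn_initmod(void (*odeparms)(int *, double *))
{
    int N = ATN_MAXPAR;
    odeparms(&N, parms);
}

/* Core evaluation shared by the solver entry point and the .Call wrapper.
 * B has length n; dB, netprod, catchrate are output arrays of length n. */
static void atn_core(const double *p, const double *B,
                     double *dB, double *netprod, double *catchrate)
{
    int n = (int) p[0];
    double K = p[1];
    const double *isprod = p + 4;
    const double *r  = p + 4 + 1 * n;
    const double *x  = p + 4 + 2 * n;
    const double *yy = p + 4 + 3 * n;
    const double *B0 = p + 4 + 4 * n;
    const double *q  = p + 4 + 5 * n;
    const double *d  = p + 4 + 6 * n;
    const double *h  = p + 4 + 7 * n;
    const double *W  = p + 4 + 8 * n;
    const double *E  = p + 4 + 8 * n + n * n;

    double Bc[ATN_MAXN], loss[ATN_MAXN], Bq[ATN_MAXN];
    int i, j;

    double prodsum = 0.0;
    for (i = 0; i < n; i++) {
        Bc[i] = (B[i] > 0.0) ? B[i] : 0.0;
        loss[i] = 0.0;
        netprod[i] = 0.0;
        if (isprod[i] > 0.5) prodsum += Bc[i];
    }
    double G = 1.0 - prodsum / K;

    for (i = 0; i < n; i++) {
        if (isprod[i] > 0.5) continue;
        double qi = q[i];
        double sumwBq = 0.0;
        int haslink = 0;
        for (j = 0; j < n; j++) {
            double w = W[i + n * j];
            if (w > 0.0) {
                double bq = (qi == 1.0) ? Bc[j] : pow(Bc[j], qi);
                Bq[j] = w * bq;
                sumwBq += Bq[j];
                haslink = 1;
            } else {
                Bq[j] = 0.0;
            }
        }
        if (!haslink) {
            /* consumer with no prey: pure metabolic decline */
            netprod[i] = -x[i] * Bc[i];
            continue;
        }
        double denom = pow(B0[i], qi) * (1.0 + d[i] * Bc[i]) + sumwBq;
        double sumF = 0.0;
        double xiyiBi = x[i] * yy[i] * Bc[i];
        for (j = 0; j < n; j++) {
            if (Bq[j] > 0.0) {
                double Fij = Bq[j] / denom;
                sumF += Fij;
                loss[j] += xiyiBi * Fij / E[i + n * j];
            }
        }
        netprod[i] = x[i] * Bc[i] * (yy[i] * sumF - 1.0);
    }

    for (i = 0; i < n; i++) {
        if (isprod[i] > 0.5)
            dB[i] = r[i] * G * Bc[i] - loss[i];
        else
            dB[i] = netprod[i] - loss[i] - h[i] * Bc[i];
        catchrate[i] = h[i] * Bc[i];
    }
}

void atn_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    int n = (int) parms[0];
    int nfish = (int) parms[3];
    const double *fishidx = parms + 4 + 8 * n + 2 * n * n;
    double dB[ATN_MAXN], netprod[ATN_MAXN], catchrate[ATN_MAXN];
    int i;

    atn_core(parms, y, dB, netprod, catchrate);
    for (i = 0; i < n; i++) ydot[i] = dB[i];
    for (i = 0; i < nfish; i++) {
        int g = (int) fishidx[i] - 1;
        ydot[n + i] = netprod[g];
        ydot[n + nfish + i] = catchrate[g];
    }
}

/* Daily event: clamp biomass components (not the auxiliary integrals)
 * below the floor eps up to eps. */
void atn_event(int *n, double *t, double *y)
{
    int ng = (int) parms[0];
    double eps = parms[2];
    int i;
    for (i = 0; i < ng; i++)
        if (y[i] < eps) y[i] = eps;
}

/* Direct single evaluation from R: takes B (length n) and the packed
 * (unpadded or padded) parameter vector; returns list(dB, netprod, catch_rate). */
SEXP atn_eval_call(SEXP BS, SEXP parmsS)
{
    int n = (int) REAL(parmsS)[0];
    if (LENGTH(BS) != n)
        error("state length %d does not match web size %d", LENGTH(BS), n);
    if (n > ATN_MAXN)
        error("web size %d exceeds compiled maximum %d", n, ATN_MAXN);

    SEXP dB = PROTECT(allocVector(REALSXP, n));
    SEXP np = PROTECT(allocVector(REALSXP, n));
    SEXP cr = PROTECT(allocVector(REALSXP, n));
    atn_core(REAL(parmsS), REAL(BS), REAL(dB), REAL(np), REAL(cr));

    SEXP out = PROTECT(allocVector(VECSXP, 3));
    SET_VECTOR_ELT(out, 0, dB);
    SET_VECTOR_ELT(out, 1, np);
    SET_VECTOR_ELT(out, 2, cr);
    SEXP nm = PROTECT(allocVector(STRSXP, 3));
    SET_STRING_ELT(nm, 0, mkChar("dB"));
    SET_STRING_ELT(nm, 1, mkChar("netprod"));
    SET_STRING_ELT(nm, 2, mkChar("catch_rate"));
    setAttrib(out, R_NamesSymbol, nm);
    UNPROTECT(5);
    return out;
}

static const R_CallMethodDef CallEntries[] = {
    {"atn_eval_call", (DL_FUNC) &atn_eval_call, 2},
    {NULL, NULL, 0}
};

static const R_CMethodDef CEntries[] = {
    {"atn_derivs",  (DL_FUNC) &atn_derivs,  6},
    {"atn_event",   (DL_FUNC) &atn_event,   3},
    {"atn_initmod", (DL_FUNC) &atn_initmod, 1},
    {NULL, NULL, 0}
};

void R_init_atnstock(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
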