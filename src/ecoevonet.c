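/* Saturating Lotka-Volterra dynamics for a bipartite mutualistic community.
 *
 * Per-capita growth of plant i:
 *   alpha_i - sum_j beta_ij N_j + (sum_k gamma_ik N_k) / (1 + h_i sum_l gamma_il N_l)
 * and symmetrically for animals. Evaluated here as a deSolve compiled
 * derivative function; parameters are staged from R through eem_set_parms()
 * before each integration (packed layout documented in R/community.R).
 */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <stdlib.h>
#include <string.h>

static double *eem_parms = NULL;
static size_t eem_parms_cap = 0;

SEXP eem_set_parms(SEXP parms)
{
    size_t n = (size_t) XLENGTH(parms);
    if (eem_parms_cap < n) {
        double *p = (double *) realloc(eem_parms, n * sizeof(double));
        if (p == NULL)
            error("allocation failure staging community parameters");
        eem_parms = p;
        eem_parms_cap = n;
    }
    memcpy(eem_parms, REAL(parms), n * sizeof(double));
    return R_NilValue;
}

/* Packed layout (all row-major):
 *   [0] nP, [1] nA,
 *   beta_P (nP*nP), beta_A (nA*nA),
 *   gamma_P (nP*nA, plant rows), gamma_A (nA*nP, animal rows),
 *   alpha_P (nP), alpha_A (nA), h_P (nP), h_A (nA)
 * State y = (N_P, N_A); negative excursions are clamped to zero so the
 * per-capita form preserves nonnegativity under roundoff.
 */
void eem_derivs(int *neq, double *t, double *y, double *ydot, double *yout, int *ip)
{
    const double *P = eem_parms;
    int nP, nA, i, j;
    const double *bP, *bA, *gP, *gA, *aP, *aA, *hP, *hA;

    if (P == NULL)
        error("community parameters have not been staged");
    nP = (int) P[0];
    nA = (int) P[1];
    bP = P + 2;
    bA = bP + (size_t) nP * nP;
    gP = bA + (size_t) nA * nA;
    gA = gP + (size_t) nP * nA;
    aP = gA + (size_t) nA * nP;
    aA = aP + nP;
    hP = aA + nA;
    hA = hP + nP;

    for (i = 0; i < nP; i++) {
        double comp = 0.0, G = 0.0;
        double Ni = y[i] > 0 ? y[i] : 0.0;
        for (j = 0; j < nP; j++) {
            double Nj = y[j] > 0 ? y[j] : 0.0;
            comp += bP[(size_t) i * nP + j] * Nj;
        }
        for (j = 0; j < nA; j++) {
            double Nk = y[nP + j] > 0 ? y[nP + j] : 0.0;
            G += gP[(size_t) i * nA + j] * Nk;
        }
        ydot[i] = Ni * (aP[i] - comp + G / (1.0 + hP[i] * G));
    }
    for (i = 0; i < nA; i++) {
        double comp = 0.0, G = 0.0;
        double Ni = y[nP + i] > 0 ? y[nP + i] : 0.0;
        for (j = 0; j < nA; j++) {
            double Nj = y[nP + j] > 0 ? y[nP + j] : 0.0;
            comp += bA[(size_t) i * nA + j] * Nj;
        }
        for (j = 0; j < nP; j++) {
            double Nk = y[j] > 0 ? y[j] : 0.0;
            G += gA[(size_t) i * nP + j] * Nk;
        }
        ydot[nP + i] = Ni * (aA[i] - comp + G / (1.0 + hA[i] * G));
    }
}

static const R_CallMethodDef CallEntries[] = {
    {"eem_set_parms", (DL_FUNC) &eem_set_parms, 1},
    {NULL, NULL, 0}
};

void R_init_ecoevonet(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE); /* deSolve looks up eem_derivs by name */
}
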