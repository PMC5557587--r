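/* Right-hand side of the logic-based ODE  dx_i/dt = (B_i(x) - x_i)/tau_i
 * evaluated from a packed parameter vector, for use through deSolve's
 * compiled-function interface.  The packed layout (all doubles) is built by
 * pack_logic_model() on the R side:
 *
 *   p[0] = n_states
 *   p[1] = normalized Hill flag (1/0)
 *   p[2 .. 2+n-1]        tau_i
 *   p[2+n .. 2+2n-1]     clamp_i   (1 -> dx_i/dt = 0)
 *   p[2+2n .. 2+3n-1]    inhib_i   (1 -> B_i forced to 0)
 *   p[2+3n .. 2+4n-1]    gcount_i  (number of selected gates of state i)
 *   p[2+4n .. 2+5n-1]    gstart_i  (0-based absolute offset of first gate)
 *   gate table: per gate  m, then m quadruples (input_index0, sign, n, k)
 *
 * B_i is the OR (multilinear, 1 - prod(1-z_e)) over the selected gates,
 * each gate the AND (product) of its Hill-transformed, sign-adjusted
 * inputs.  State values are clamped into [0,1] before the Hill transform so
 * that small integrator overshoots cannot produce NaN from pow().
 */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

static SEXP logic_parms = NULL;

SEXP C_set_logic_parms(SEXP p)
{
    if (TYPEOF(p) != REALSXP)
        error("packed parameter vector must be numeric");
    SEXP d = PROTECT(duplicate(p));
    if (logic_parms != NULL)
        R_ReleaseObject(logic_parms);
    R_PreserveObject(d);
    logic_parms = d;
    UNPROTECT(1);
    return R_NilValue;
}

void C_logic_derivs(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    if (logic_parms == NULL)
        error("logic model parameters not set");
    const double *p = REAL(logic_parms);
    const int n = (int) p[0];
    const int norm = (int) p[1];
    const double *tau    = p + 2;
    const double *clampv = p + 2 + n;
    const double *inhib  = p + 2 + 2 * n;
    const double *gcount = p + 2 + 3 * n;
    const double *gstart = p + 2 + 4 * n;

    for (int i = 0; i < n; i++) {
        if (clampv[i] > 0.5) { ydot[i] = 0.0; continue; }
        double B = 0.0;
        int ng = (inhib[i] > 0.5) ? 0 : (int) gcount[i];
        if (ng > 0) {
            double prod_off = 1.0;
            int off = (int) gstart[i];
            for (int g = 0; g < ng; g++) {
                int m = (int) p[off]; off++;
                double z = 1.0;
                for (int j = 0; j < m; j++) {
                    int    xi = (int) p[off];
                    double sg = p[off + 1];
                    double hn = p[off + 2];
                    double hk = p[off + 3];
                    off += 4;
                    double x = y[xi];
                    if (x < 0.0) x = 0.0;
                    if (x > 1.0) x = 1.0;
                    double f;
                    if (x == 0.0) {
                        f = 0.0;
                    } else {
                        double xn = pow(x, hn), kn = pow(hk, hn);
                        f = xn / (xn + kn);
                        if (norm) f *= (1.0 + kn);   /* / f_H(1) */
                    }
                    if (sg < 0.0) f = 1.0 - f;
                    z *= f;
                }
                prod_off *= (1.0 - z);
            }
            B = 1.0 - prod_off;
        }
        ydot[i] = (B - y[i]) / tau[i];
    }
}

static const R_CallMethodDef call_entries[] = {
    {"C_set_logic_parms", (DL_FUNC) &C_set_logic_parms, 1},
    {NULL, NULL, 0}
};

/* registered so deSolve can look the derivative function up by name */
static const R_CMethodDef c_entries[] = {
    {"C_logic_derivs", (DL_FUNC) &C_logic_derivs, 6},
    {NULL, NULL, 0}
};

void R_init_logicess(DllInfo *dll)
{
    R_registerRoutines(dll, c_entries, call_entries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
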