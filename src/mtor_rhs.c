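/* Compiled right-hand side of the stress-mTORC1 network for deSolve.
 *
 * The flat parameter vector is packed by the R side (.packParms): reaction
 * multiplicity, MK-2206 scaling, wortmannin zeroing and the stress step are
 * already folded into the per-reaction effective rate constants, so the
 * system is autonomous.  Species indices follow the canonical order.
 */
#include <R.h>

#define NPARMS 256
#define NSPEC  25

static double parms[NPARMS];

/* canonical 0-based species indices used by the activity expressions */
#define IR_PY1146   1
#define IRS1_LOC    3
#define PI3K_P      6
#define PDK1_MEM    8
#define AKT_PT308   10
#define AKT_PS473   11
#define AKT_DBL     12
#define TSC2_0      13
#define PRAS40_0    15
#define S6K_PT389   21
#define S6K_DBL     22

void mtor_init(void (*odeparms)(int *, double *))
{
    int n = NPARMS;
    odeparms(&n, parms);
}

static double frac(double num, double den)
{
    return (den > 0.0) ? num / den : 0.0;
}

void mtor_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    int    nr = (int) parms[0];
    double s  = parms[1];
    const double *C = parms + 2;        /* 9 pool totals */
    double pre_c1   = parms[11];
    double insulin  = parms[12];
    const double *rx = parms + 13;      /* 5 slots per reaction */
    double x[NSPEC], act[10];
    int i;

    for (i = 0; i < NSPEC; i++) {
        x[i] = (y[i] > 0.0) ? y[i] : 0.0;
        ydot[i] = 0.0;
    }

    /* pools: 0 IR, 1 IRS1, 2 PI3K, 3 PDK1, 4 Akt, 5 TSC2, 6 PRAS40,
       7 p70_S6K, 8 4EBP1 */
    act[0] = 1.0;                                   /* none */
    act[1] = frac(x[PI3K_P], C[2]);                 /* mTORC2 = A_PI3K */
    act[2] = frac(x[PDK1_MEM], C[3]);               /* PDK1 */
    act[3] = frac(x[AKT_PT308] + s * x[AKT_PS473] + 2.0 * x[AKT_DBL],
                  C[4]);                            /* Akt */
    {
        double r1 = 1.0 - frac(x[TSC2_0], C[5]);
        double r2 = 1.0 - frac(x[PRAS40_0], C[6]);
        if (r1 < 0.0) r1 = 0.0;
        if (r2 < 0.0) r2 = 0.0;
        act[4] = pre_c1 * r1 * r2;                  /* mTORC1 */
    }
    act[5] = frac(x[S6K_PT389] + x[S6K_DBL], C[7]); /* S6K */
    act[6] = frac(x[IR_PY1146], C[0]);              /* IR */
    act[7] = frac(x[IRS1_LOC], C[1]);               /* IRS1 */
    act[8] = insulin;                               /* insulin input */
    act[9] = act[1];                                /* PI3K */

    for (i = 0; i < nr; i++) {
        int    sub  = (int) rx[5 * i];
        int    prod = (int) rx[5 * i + 1];
        double k    = rx[5 * i + 2];
        int    code = (int) rx[5 * i + 3];
        double kst  = rx[5 * i + 4];
        double v    = (k * act[code] + kst) * x[sub];
        ydot[sub]  -= v;
        ydot[prod] += v;
    }
}
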