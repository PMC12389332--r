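/* Reduced whole-body PBPK model: segmental gut with enterocyte efflux and
 * gut metabolism, optional permeability-limited liver with active uptake,
 * central + muscle, renal filtration and active secretion, optional
 * first-order prodrug conversion. State amounts in mg, time in h.
 *
 * State layout (19):
 *  0 stomach lumen        7 prodrug pool          14 elim: biliary
 *  1 jejunum lumen        8 liver extracellular   15 elim: renal filtration
 *  2 ileum lumen          9 liver intracellular   16 elim: renal secretion
 *  3 colon lumen         10 central (plasma)      17 elim: systemic extra
 *  4 jejunum enterocyte  11 muscle                18 elim: fecal
 *  5 ileum enterocyte    12 elim: gut metabolism
 *  6 colon enterocyte    13 elim: hepatic metabolism
 *
 * Parameter layout (32): see buildPbpkParams() on the R side.
 */
#include <R.h>

#define NPARMS 32

static double parms[NPARMS];

#define k_ge     parms[0]
#define k_jt     parms[1]
#define k_it     parms[2]
#define k_ct     parms[3]
#define ka_j     parms[4]
#define ka_i     parms[5]
#define ka_c     parms[6]
#define k_bas    parms[7]
#define V_ent    parms[8]
#define CLeff_j  parms[9]
#define CLeff_i  parms[10]
#define CLeff_c  parms[11]
#define CLmet_j  parms[12]
#define CLmet_i  parms[13]
#define CLmet_c  parms[14]
#define k_conv   parms[15]
#define Q_h      parms[16]
#define V_ec     parms[17]
#define V_ic     parms[18]
#define PS_l     parms[19]
#define CL_upt   parms[20]
#define CLmet_h  parms[21]
#define CL_bil   parms[22]
#define fu       parms[23]
#define Vc       parms[24]
#define Q_m      parms[25]
#define Vm       parms[26]
#define kp_m     parms[27]
#define CL_filt  parms[28]
#define CL_sec   parms[29]
#define cl_extra parms[30]
#define has_liv  parms[31]

void pbpk_initmod(void (*odeparms)(int *, double *))
{
    int n = NPARMS;
    odeparms(&n, parms);
}

void pbpk_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    double Cp = y[10] / Vc;
    double Fabs = k_bas * (y[4] + y[5] + y[6]);
    double formed = k_conv * y[7];
    double Jm = 0.0, Jh = 0.0;

    /* gut lumen + transit */
    ydot[0] = -k_ge * y[0];
    ydot[1] = k_ge * y[0] - (k_jt + ka_j) * y[1] + (CLeff_j / V_ent) * y[4];
    ydot[2] = k_jt * y[1] - (k_it + ka_i) * y[2] + (CLeff_i / V_ent) * y[5];
    ydot[3] = k_it * y[2] - (k_ct + ka_c) * y[3] + (CLeff_c / V_ent) * y[6];
    ydot[18] = k_ct * y[3];

    /* enterocytes: basolateral exit vs apical efflux vs gut metabolism */
    ydot[4] = ka_j * y[1] - (k_bas + (CLeff_j + CLmet_j) / V_ent) * y[4];
    ydot[5] = ka_i * y[2] - (k_bas + (CLeff_i + CLmet_i) / V_ent) * y[5];
    ydot[6] = ka_c * y[3] - (k_bas + (CLeff_c + CLmet_c) / V_ent) * y[6];
    ydot[12] = (CLmet_j * y[4] + CLmet_i * y[5] + CLmet_c * y[6]) / V_ent;

    /* prodrug pool: absorbed prodrug converts first-order to the active
     * moiety, which enters the systemic circulation */
    if (k_conv > 0.0)
        ydot[7] = Fabs - formed;
    else
        ydot[7] = 0.0;

    if (has_liv > 0.5) {
        double Cec = y[8] / V_ec;
        double Cic = y[9] / V_ic;
        double influx = (PS_l + CL_upt) * fu * Cec;
        double back = PS_l * Cic;
        Jh = Q_h * (Cp - Cec);
        ydot[8] = Jh - influx + back + (k_conv > 0.0 ? 0.0 : Fabs);
        ydot[9] = influx - back - (CLmet_h + CL_bil) * Cic;
        ydot[13] = CLmet_h * Cic;
        ydot[14] = CL_bil * Cic;
    } else {
        ydot[8] = 0.0;
        ydot[9] = 0.0;
        ydot[13] = 0.0;
        ydot[14] = 0.0;
    }

    if (kp_m > 0.0)
        Jm = Q_m * (Cp - y[11] / (Vm * kp_m));
    ydot[11] = Jm;

    ydot[10] = -Jh - Jm - (CL_filt + CL_sec + cl_extra) * Cp;
    if (k_conv > 0.0)
        ydot[10] += formed;
    else if (has_liv <= 0.5)
        ydot[10] += Fabs;

    ydot[15] = CL_filt * Cp;
    ydot[16] = CL_sec * Cp;
    ydot[17] = cl_extra * Cp;
}
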