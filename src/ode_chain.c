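/* Compiled right-hand side for the reversible condensation chains, used
 * by deSolve.  Parameter vector layout (padded to length 13):
 *   parms[0]            number of steps (1..4)
 *   parms[1..nstep]     reaction order per step
 *   parms[1+n..2n]      forward (aggregation) rates
 *   parms[1+2n..3n]     backward (dissolution) rates
 */
#include <R.h>
#include <Rmath.h>

#define ROM_PARMS_LEN 13
static double rom_parms[ROM_PARMS_LEN];

void rom_initmod(void (*odeparms)(int *, double *)) {
  int n = ROM_PARMS_LEN;
  odeparms(&n, rom_parms);
}

void rom_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip) {
  int nstep = (int) rom_parms[0];
  for (int i = 0; i <= nstep; i++) ydot[i] = 0.0;
  for (int i = 0; i < nstep; i++) {
    double k = rom_parms[1 + i];
    double fwd = rom_parms[1 + nstep + i] * R_pow(y[i], k);
    double bwd = rom_parms[1 + 2 * nstep + i] * y[i + 1];
    ydot[i] += k * (bwd - fwd);
    ydot[i + 1] += fwd - bwd;
  }
}
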