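#ifndef BFMETH_POLYAGAMMA_H
#define BFMETH_POLYAGAMMA_H

double rpg_one(double z);
double rpg(int b, double z, int exact_max);

#endif
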