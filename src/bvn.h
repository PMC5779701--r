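#ifndef LONGNET_BVN_H
#define LONGNET_BVN_H

// P(X <= h, Y <= k) for standard bivariate normal with correlation rho.
// Handles infinite limits and |rho| = 1 exactly.
double bvn_cdf(double h, double k, double rho);

#endif
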