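{
  "comment": "Published seven-descriptor linear discriminant equation for ERK-1/2 inhibitor classification over Box-Jenkins deviation descriptors; encoded as printed (the hydrophobicity term is the stochastic index Tssq2(HYD)N1).",
  "intercept": 1.653,
  "coefficients": {
    "D[Tnsq5(CH)N2]me": -0.080,
    "D[Tnsq3(CH)MN]bt": -1.842,
    "D[Tssq11(CH)MN]me": 18.180,
    "D[Tssq5(POL)MX]me": -0.027,
    "D[Tnsq1(PSA)GM]me": 0.005,
    "D[Tnsq13(VDW)N2]bt": 0.003,
    "D[Tssq2(HYD)N1]me": -0.111
  },
  "stats": {
    "lambda": 0.397,
    "canonical_R": 0.776,
    "chi_square": 3302.20,
    "mahalanobis_D2": 6.54
  },
  "n": 3585
}
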