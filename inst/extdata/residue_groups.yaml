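# Residue group memberships used by the physicochemical property composition
# (PCP) block. Groups follow standard biochemical classifications:
# charge groups from side-chain pKa at physiological pH (His counted basic),
# hydrophobicity groups from the CTD descriptor convention, size groups from
# Taylor's Venn classification, and secondary-structure propensity groups from
# Chou-Fasman conformational parameters (P > ~1.05). "Intermediate" collects
# residues with no strong helix/sheet/turn preference.
groups:
  Positive: [K, R, H]
  Negative: [D, E]
  Polar: [D, E, H, K, "N", Q, R, S, T, "Y"]
  NonPolar: [A, C, F, G, I, L, M, P, V, W]
  Hydrophobic: [C, F, I, L, M, V, W]
  Hydrophilic: [D, E, K, "N", Q, R]
  Aromatic: [F, W, "Y", H]
  Aliphatic: [A, G, I, L, V]
  Sulfur: [C, M]
  Tiny: [A, C, G, S, T]
  Small: [A, C, D, G, "N", P, S, T, V]
  Large: [E, F, H, I, K, L, M, Q, R, W, "Y"]
  Charged: [K, R, H, D, E]
  Neutral: [A, C, F, G, I, L, M, "N", P, Q, S, T, V, W, "Y"]
  Flexible: [D, E, G, K, "N", P, Q, R, S, T]
  Rigid: [A, C, F, H, I, L, M, V, W, "Y"]
  HelixFormer: [A, E, F, I, K, L, M, Q, V, W]
  SheetFormer: [C, F, I, L, M, Q, T, V, W, "Y"]
  TurnFormer: [C, D, G, K, "N", P, S, "Y"]
  Intermediate: [H, R]
# Integer side-chain charges at physiological pH (His counted +1, consistent
# with its membership in the Positive group above).
charge:
  K: 1
  R: 1
  H: 1
  D: -1
  E: -1
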