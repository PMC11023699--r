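# Five-factor PANSS alternative (Positive, Negative, Disorganization,
# Excitement, Emotional Distress), arranged as a full partition of the 30
# items so subscale sums remain comparable with the three-factor scheme.
Positive: [P1, P3, P5, P6, G1, G9, G12]
Negative: [N1, N2, N3, N4, N6, N7, G16]
Disorganization: [P2, N5, G5, G10, G11, G13, G15]
Excitement: [P4, P7, G4, G8, G14]
EmotionalDistress: [G2, G3, G6, G7]
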