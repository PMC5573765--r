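{
  "description": "Calibrated RCR Windkessel parameters for the two inner-curvature AVF configurations; clinical units (resistances mmHg.mL^-1.s, compliances mL/mmHg).",
  "P1-IN": {
    "R1_RAO": 6.88, "R2_RAO": 59.80, "C_RAO": 0.010,
    "R1_UAO": 6.88, "R2_UAO": 59.80, "C_UAO": 0.010,
    "R1_VO": 7.00, "R2_VO": 10.30, "C_VO": 10.50
  },
  "P2-IN": {
    "R1_RAO": 3.20, "R2_RAO": 53.20, "C_RAO": 0.009,
    "R1_UAO": 3.20, "R2_UAO": 53.20, "C_UAO": 0.009,
    "R1_VO": 7.00, "R2_VO": 7.50, "C_VO": 5.25
  }
}
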