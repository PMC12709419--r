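{
  "version": "1.0",
  "comment": "Membrane rate constants are whole-cell (per Schwann cell) conductances in uL/s; D as printed in m^2/s.",
  "presets": [
    {"drug": "lidocaine",   "condition": "physiological", "D_m2_s": 7.49e-10, "k_EN": 9.147e-3, "k_NE": 2.152e-4},
    {"drug": "lidocaine",   "condition": "acidosis",      "D_m2_s": 7.49e-10, "k_EN": 2.322e-2, "k_NE": 1.942e-3},
    {"drug": "bupivacaine", "condition": "physiological", "D_m2_s": 6.71e-10, "k_EN": 3.774e-3, "k_NE": 1.093e-5},
    {"drug": "bupivacaine", "condition": "acidosis",      "D_m2_s": 6.71e-10, "k_EN": 6.948e-3, "k_NE": 7.127e-5}
  ]
}
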