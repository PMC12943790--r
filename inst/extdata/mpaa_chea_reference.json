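{
  "label": "mpaa_chea_reference",
  "description": "Literature reference point: resolution of racemic 2-methoxy-2-phenylacetic acid (MPAA) with (R)-1-cyclohexylethylamine. Only the published summary metrics are stored (no thermodynamic table is available here): salt-pair eutectic composition x_eu = 0.30 of the favored salt, a ca. 25 K melting point gap, and the corresponding Fogassy parameter F_max = 0.57. Exercises the resolvability metrics only.",
  "components": ["(S)-MPAA", "(R)-MPAA", "(R)-CHEA"],
  "reference": {
    "x_eu": 0.30,
    "delta_Tm": 25,
    "F_max": 0.57,
    "provenance": {
      "x_eu": "published eutectic molar composition of the favored diastereomeric salt",
      "delta_Tm": "published ca. 25 C melting point difference of the salt pair",
      "F_max": "published resolubility value, F_max = 2 - 1/(1 - x_eu) = 0.57"
    }
  }
}
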