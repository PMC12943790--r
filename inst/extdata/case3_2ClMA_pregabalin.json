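{
  "label": "case3_2ClMA_pregabalin",
  "description": "Resolution system of racemic 2-chloromandelic acid with (S)-pregabalin. No double salt; the diastereomeric salt pair melts 50 K apart, giving a strongly asymmetric diagram and a promising resolution. Salt and agent enthalpies were reported as decomposition-corrected specific values (J/g) and are converted to J/mol at load time via the molar masses from the chemical formulas; the enthalpy-to-phase mapping (75 J/g to the 100 C salt, 171 J/g to the 150 C salt, 312 J/g to pregabalin) follows the parallel order of the published melting-point and enthalpy lists.",
  "components": ["(S)-2ClMA", "(R)-2ClMA", "(S)-pregabalin"],
  "phases": [
    {
      "name": "1''", "role": "enantiomer", "coords": [1, 0, 0],
      "formula": "C8H7ClO3",
      "t_fus": 393.1, "t_fus_unit": "K", "dh_fus": 24033, "dh_fus_unit": "J/mol",
      "provenance": {
        "t_fus": "published DSC peak temperature of (S)-2-chloromandelic acid, 120 C / 393.1 K",
        "dh_fus": "published molar enthalpy of fusion, 24033 J/mol",
        "coords": "pure enantiomer corner"
      }
    },
    {
      "name": "3''", "role": "enantiomer", "coords": [0, 1, 0],
      "formula": "C8H7ClO3",
      "t_fus": 393.1, "t_fus_unit": "K", "dh_fus": 24033, "dh_fus_unit": "J/mol",
      "provenance": {
        "t_fus": "assumed identical to the (S)-enantiomer",
        "dh_fus": "assumed identical to the (S)-enantiomer",
        "coords": "pure enantiomer corner"
      }
    },
    {
      "name": "2''", "role": "racemic_compound", "coords": [0.5, 0.5, 0],
      "t_fus": 362.1, "t_fus_unit": "K", "dh_fus": 43076, "dh_fus_unit": "J/mol",
      "provenance": {
        "t_fus": "published DSC peak temperature of rac-2-chloromandelic acid, 89 C / 362.1 K",
        "dh_fus": "published molar enthalpy of fusion, 43076 J/mol",
        "coords": "1:1 racemic compound, midpoint of the enantiomer edge"
      }
    },
    {
      "name": "4''", "role": "diastereomeric_salt", "coords": [0.5, 0, 0.5],
      "formula": "C16H24ClNO5",
      "t_fus": 150, "t_fus_unit": "C", "dh_fus": 171, "dh_fus_unit": "J/g",
      "provenance": {
        "t_fus": "observed DSC melting point of the separately prepared (S)-pregabalin-(S)-2-chloromandelic acid salt, 150 C",
        "dh_fus": "DERIVED: decomposition-corrected specific enthalpy 171 J/g x molar mass of C16H24ClNO5 (345.82 g/mol)",
        "coords": "1:1 salt of enantiomer 1 with pregabalin"
      }
    },
    {
      "name": "5''", "role": "diastereomeric_salt", "coords": [0, 0.5, 0.5],
      "formula": "C16H24ClNO5",
      "t_fus": 100, "t_fus_unit": "C", "dh_fus": 75, "dh_fus_unit": "J/g",
      "provenance": {
        "t_fus": "observed DSC melting point of the separately prepared (S)-pregabalin-(R)-2-chloromandelic acid salt, 100 C",
        "dh_fus": "DERIVED: decomposition-corrected specific enthalpy 75 J/g x molar mass of C16H24ClNO5 (345.82 g/mol)",
        "coords": "1:1 salt of enantiomer 2 with pregabalin"
      }
    },
    {
      "name": "6''", "role": "resolving_agent", "coords": [0, 0, 1],
      "formula": "C8H17NO2",
      "t_fus": 199, "t_fus_unit": "C", "dh_fus": 312, "dh_fus_unit": "J/g",
      "provenance": {
        "t_fus": "observed DSC melting point of (S)-pregabalin, 199 C (melting escorted by decomposition)",
        "dh_fus": "DERIVED: decomposition-corrected specific enthalpy 312 J/g x molar mass of C8H17NO2 (159.23 g/mol)",
        "coords": "pure resolving-agent corner"
      }
    }
  ]
}
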