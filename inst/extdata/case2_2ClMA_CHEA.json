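{
  "label": "case2_2ClMA_CHEA",
  "description": "Resolution system of racemic 2-chloromandelic acid with (S)-1-cyclohexylethylamine (CHEA). Six crystalline phases including a 2 amine : 1 acid double salt; DSC data from the published binary melting diagrams of the chloromandelic acids and the diastereomeric-salt screening study of this system.",
  "components": ["(S)-2ClMA", "(R)-2ClMA", "(S)-CHEA"],
  "phases": [
    {
      "name": "1'", "role": "enantiomer", "coords": [1, 0, 0],
      "formula": "C8H7ClO3",
      "t_fus": 393.1, "t_fus_unit": "K", "dh_fus": 24033, "dh_fus_unit": "J/mol",
      "provenance": {
        "t_fus": "published DSC peak temperature of (S)-2-chloromandelic acid, 120 C / 393.1 K",
        "dh_fus": "published molar enthalpy of fusion, 24033 J/mol",
        "coords": "pure enantiomer corner"
      }
    },
    {
      "name": "3'", "role": "enantiomer", "coords": [0, 1, 0],
      "formula": "C8H7ClO3",
      "t_fus": 393.1, "t_fus_unit": "K", "dh_fus": 24033, "dh_fus_unit": "J/mol",
      "provenance": {
        "t_fus": "assumed identical to the (S)-enantiomer, as in the source data table",
        "dh_fus": "assumed identical to the (S)-enantiomer",
        "coords": "pure enantiomer corner"
      }
    },
    {
      "name": "2'", "role": "racemic_compound", "coords": [0.5, 0.5, 0],
      "t_fus": 362.1, "t_fus_unit": "K", "dh_fus": 43076, "dh_fus_unit": "J/mol",
      "provenance": {
        "t_fus": "published DSC peak temperature of rac-2-chloromandelic acid, 89 C / 362.1 K",
        "dh_fus": "published molar enthalpy of fusion, 43076 J/mol",
        "coords": "1:1 racemic compound, midpoint of the enantiomer edge"
      }
    },
    {
      "name": "4'", "role": "diastereomeric_salt", "coords": [0.5, 0, 0.5],
      "t_fus": 413.1, "t_fus_unit": "K", "dh_fus": 13200, "dh_fus_unit": "J/mol",
      "provenance": {
        "t_fus": "published DSC peak temperature of the S-S CHEA salt of 2ClMA, 140 C / 413.1 K",
        "dh_fus": "published molar enthalpy of fusion, 13200 J/mol; carried as printed although an order of magnitude below the 4ClMA salts",
        "coords": "1:1 salt of enantiomer 1 with the resolving agent"
      }
    },
    {
      "name": "6'", "role": "diastereomeric_salt", "coords": [0, 0.5, 0.5],
      "t_fus": 400.6, "t_fus_unit": "K", "dh_fus": 13714, "dh_fus_unit": "J/mol",
      "provenance": {
        "t_fus": "published DSC peak temperature of the S-R CHEA salt of 2ClMA, 127.5 C / 400.6 K",
        "dh_fus": "published molar enthalpy of fusion, 13714 J/mol; carried as printed although an order of magnitude below the 4ClMA salts",
        "coords": "1:1 salt of enantiomer 2 with the resolving agent"
      }
    },
    {
      "name": "5'", "role": "double_salt", "coords": [0.25, 0.25, 0.5],
      "t_fus": 424.6, "t_fus_unit": "K", "dh_fus": 54832, "dh_fus_unit": "J/mol",
      "provenance": {
        "t_fus": "published DSC peak temperature of the (S)2-(S&R) double salt of 2ClMA, 151.5 C / 424.6 K",
        "dh_fus": "published molar enthalpy of fusion, 54832 J/mol",
        "coords": "2 amine : 1 R-acid : 1 S-acid addition compound at the 1:1 racemate:agent test point"
      }
    }
  ]
}
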