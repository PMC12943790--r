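{
  "label": "case1_4ClMA_CHEA",
  "description": "Resolution system of racemic 4-chloromandelic acid with (S)-1-cyclohexylethylamine (CHEA). Six crystalline phases including a 2 amine : 1 acid double salt of the diastereomeric salt pair; DSC peak temperatures and molar enthalpies of fusion from the published binary melting diagrams of the chloromandelic acids and the diastereomeric-salt screening study of this system.",
  "components": ["(S)-4ClMA", "(R)-4ClMA", "(S)-CHEA"],
  "phases": [
    {
      "name": "1", "role": "enantiomer", "coords": [1, 0, 0],
      "formula": "C8H7ClO3",
      "t_fus": 396.3, "t_fus_unit": "K", "dh_fus": 21850, "dh_fus_unit": "J/mol",
      "provenance": {
        "t_fus": "published DSC peak temperature of (S)-4-chloromandelic acid, 123.2 C / 396.3 K",
        "dh_fus": "published molar enthalpy of fusion, 21850 J/mol",
        "coords": "pure enantiomer corner of the composition triangle"
      }
    },
    {
      "name": "3", "role": "enantiomer", "coords": [0, 1, 0],
      "formula": "C8H7ClO3",
      "t_fus": 396.3, "t_fus_unit": "K", "dh_fus": 21850, "dh_fus_unit": "J/mol",
      "provenance": {
        "t_fus": "assumed identical to the (S)-enantiomer, as in the source data table",
        "dh_fus": "assumed identical to the (S)-enantiomer",
        "coords": "pure enantiomer corner"
      }
    },
    {
      "name": "2", "role": "racemic_compound", "coords": [0.5, 0.5, 0],
      "t_fus": 395.4, "t_fus_unit": "K", "dh_fus": 50418, "dh_fus_unit": "J/mol",
      "provenance": {
        "t_fus": "published DSC peak temperature of rac-4-chloromandelic acid, 122.4 C / 395.4 K",
        "dh_fus": "published molar enthalpy of fusion, 50418 J/mol",
        "coords": "1:1 addition compound of the enantiomers, midpoint of the enantiomer edge"
      }
    },
    {
      "name": "4", "role": "diastereomeric_salt", "coords": [0.5, 0, 0.5],
      "t_fus": 434.1, "t_fus_unit": "K", "dh_fus": 31585, "dh_fus_unit": "J/mol",
      "provenance": {
        "t_fus": "published DSC peak temperature of the S(R)-S(R) CHEA salt of 4ClMA, 161 C / 434.1 K",
        "dh_fus": "published molar enthalpy of fusion, 31585 J/mol",
        "coords": "1:1 salt of enantiomer 1 with the resolving agent, counted in mole fractions of molecules"
      }
    },
    {
      "name": "6", "role": "diastereomeric_salt", "coords": [0, 0.5, 0.5],
      "t_fus": 430.1, "t_fus_unit": "K", "dh_fus": 26736, "dh_fus_unit": "J/mol",
      "provenance": {
        "t_fus": "published DSC peak temperature of the S-R CHEA salt of 4ClMA, 157 C / 430.1 K",
        "dh_fus": "published molar enthalpy of fusion, 26736 J/mol",
        "coords": "1:1 salt of enantiomer 2 with the resolving agent"
      }
    },
    {
      "name": "5", "role": "double_salt", "coords": [0.25, 0.25, 0.5],
      "t_fus": 415.1, "t_fus_unit": "K", "dh_fus": 65680, "dh_fus_unit": "J/mol",
      "provenance": {
        "t_fus": "published DSC peak temperature of the (S)2-(S&R) double salt of 4ClMA, 142 C / 415.1 K",
        "dh_fus": "published molar enthalpy of fusion, 65680 J/mol",
        "coords": "2 amine : 1 R-acid : 1 S-acid addition compound: 0.25/0.25/0.5 in mole fractions of molecules, coinciding with the 1:1 racemate:agent test point"
      }
    }
  ]
}
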