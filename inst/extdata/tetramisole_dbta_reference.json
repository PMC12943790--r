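{
  "label": "tetramisole_dbta_reference",
  "description": "Topology-only reference: resolution of racemic tetramisole base with O,O'-dibenzoyl-(R,R)-tartaric acid (DBTA). Eight crystalline phases including a 1:1 double salt at the test point AND a 2:1 base:acid salt that opens an escape route for resolution at sub-stoichiometric acid. No thermodynamic data are published for these phases, so this fixture carries coordinates and roles only and exercises triangulation and verdict degradation (indeterminate without melting data).",
  "components": ["(S)-TET", "(R)-TET", "(R,R)-DBTA"],
  "phases": [
    { "name": "S-TET", "role": "enantiomer", "coords": [1, 0, 0],
      "provenance": { "coords": "pure enantiomer corner" } },
    { "name": "R-TET", "role": "enantiomer", "coords": [0, 1, 0],
      "provenance": { "coords": "pure enantiomer corner" } },
    { "name": "rac-TET", "role": "racemic_compound", "coords": [0.5, 0.5, 0],
      "provenance": { "coords": "racemate to be resolved, midpoint of the enantiomer edge" } },
    { "name": "DBTA", "role": "resolving_agent", "coords": [0, 0, 1],
      "provenance": { "coords": "pure resolving-agent corner" } },
    { "name": "1 (I)", "role": "other_salt", "coords": [0.6666666666666666, 0, 0.3333333333333333],
      "provenance": { "coords": "2:1 base:acid salt of (S)-tetramisole with DBTA: 2/3 base, 1/3 acid on the enantiomer-agent edge; the key phase of the published successful resolution" } },
    { "name": "2 (II)", "role": "diastereomeric_salt", "coords": [0.5, 0, 0.5],
      "provenance": { "coords": "expected 1:1 diastereomeric salt of enantiomer 1" } },
    { "name": "4 (IV)", "role": "diastereomeric_salt", "coords": [0, 0.5, 0.5],
      "provenance": { "coords": "expected 1:1 diastereomeric salt of enantiomer 2" } },
    { "name": "3 (III)", "role": "double_salt", "coords": [0.25, 0.25, 0.5],
      "provenance": { "coords": "1:1 double salt of the two enantiomers with DBTA, at the 1:1 racemate:agent test point" } }
  ]
}
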