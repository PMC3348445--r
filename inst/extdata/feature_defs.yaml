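# Default hydrogen-bonding feature definitions.
#
# Each entry: name, kind (donor/acceptor/custom/constraint), a SMARTS string
# in the supported subset, the pattern-atom position carrying the feature
# (`atom`, default 1), a strength (strong is reserved for ionised groups;
# thiourea sulfur, thiol and activated C-H are weak) and a hydrogen-bond
# geometry class (trigonal, tetrahedral_cone, linear, planar_arc, cone,
# none). For a given kind the first matching definition per atom wins, so
# order from specific/ionised to generic. Hydrophobes are perceived by
# built-in rules, not listed here.
features:
  # --- donors ---
  - name: ionised_N_donor          # ammonium, amidinium, guanidinium
    kind: donor
    smarts: "[N+;!H0]"
    strength: strong
    geometry: tetrahedral_cone
  - name: amide_NH
    kind: donor
    smarts: "[NX3;+0;!H0][CX3]=[OX1]"
    strength: medium
    geometry: trigonal
  - name: aromatic_NH
    kind: donor
    smarts: "[n;!H0]"
    strength: medium
    geometry: trigonal
  - name: amine_NH
    kind: donor
    smarts: "[NX3;+0;!H0]"
    strength: medium
    geometry: tetrahedral_cone
  - name: hydroxyl_OH
    kind: donor
    smarts: "[OX2;+0;!H0]"
    strength: medium
    geometry: tetrahedral_cone
  - name: thiol_SH
    kind: donor
    smarts: "[SX2;!H0]"
    strength: weak
    geometry: tetrahedral_cone
  - name: activated_CH              # e.g. the 2 position of pyrimidine
    kind: donor
    smarts: "n[cH1]n"
    atom: 2
    strength: weak
    geometry: trigonal
  # --- acceptors ---
  - name: ionised_O_acceptor        # carboxylate, phosphate, sulfonate O-
    kind: acceptor
    smarts: "[OX1-]"
    strength: strong
    geometry: cone
  - name: carbonyl_O
    kind: acceptor
    smarts: "[OX1]=[CX3]"
    strength: medium
    geometry: planar_arc
  - name: oxo_O                     # P=O, S=O and other terminal oxygens
    kind: acceptor
    smarts: "[OX1;+0]"
    strength: medium
    geometry: cone
  - name: ether_or_hydroxyl_O
    kind: acceptor
    smarts: "[OX2;+0]"
    strength: medium
    geometry: tetrahedral_cone
  - name: nitrile_N
    kind: acceptor
    smarts: "[NX1]#[#6]"
    strength: medium
    geometry: linear
  - name: aromatic_N_acceptor       # two-coordinate sp2 nitrogen
    kind: acceptor
    smarts: "[nX2;H0;+0]"
    strength: medium
    geometry: trigonal
  - name: imine_N
    kind: acceptor
    smarts: "[NX2;+0]=[#6]"
    strength: medium
    geometry: trigonal
  - name: thiocarbonyl_S
    kind: acceptor
    smarts: "[SX1]=[#6]"
    strength: weak
    geometry: planar_arc
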