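# Rotatable-bond rules.
#
# Each rule: a SMARTS pattern plus the two pattern-atom positions forming the
# bond. `exclude: true` vetoes matching bonds; `min_deg`/`max_deg` with
# `torsion_atoms` restrict the allowed torsion range (degrees, interval may
# wrap through 180). Bonds must additionally be single, non-aromatic and
# acyclic; that is enforced in code, not here.
rules:
  - name: acyclic-single
    smarts: "[!#1;!D1]-[!#1;!D1]"
    bond_atoms: [1, 2]
  - name: methyl
    smarts: "[CX4H3]-[!#1]"
    bond_atoms: [1, 2]
    exclude: true
  - name: ester-trans
    # C-O-C=O held within 5 degrees of the trans planar geometry
    smarts: "[#6]-[OX2]-[CX3]=[OX1]"
    bond_atoms: [2, 3]
    torsion_atoms: [1, 2, 3, 4]
    min_deg: 175
    max_deg: -175
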