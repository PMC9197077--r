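# Sample plugin definitions: six additional interaction types.
# SMARTS patterns and thresholds are documented reconstructions chosen to
# express the named interaction classes; adjust them to your protocol.
plugins:
  - name: any
    # any heavy-atom contact between nucleic acid and ligand
    receptor_smarts: "[!#1]"
    ligand_smarts: "[!#1]"
    criterion:
      type: distance
      dmin: 0.0
      dmax: 4.0
  - name: polar
    # hydrogen bonds without angle restraints: any N/O pair
    receptor_smarts: "[#7,#8]"
    ligand_smarts: "[#7,#8,#16]"
    criterion:
      type: distance
      dmin: 0.0
      dmax: 3.9
  - name: weak_polar
    # carbon donor to N/O acceptor, no angle restraint
    receptor_smarts: "[#6;!H0]"
    ligand_smarts: "[#7,#8]"
    criterion:
      type: distance
      dmin: 0.0
      dmax: 3.8
  - name: n_pi_star
    # lone pair donation into a carbonyl pi* orbital along the
    # Buergi-Dunitz trajectory (angle window around 107 degrees at the
    # carbonyl carbon)
    receptor_smarts: "[#7,#8]"
    ligand_smarts: "[CX3]=[OX1]"
    criterion:
      type: distance_angle
      dmin: 0.0
      dmax: 3.6
      amin: 95
      amax: 125
      anchors: [R1, L1, L2]
  - name: weak_hydrogen_bonds
    # C-H...O/N with a directional angle at the hydrogen-bearing carbon
    receptor_smarts: "[#6;!H0][#1]"
    ligand_smarts: "[#7,#8]"
    criterion:
      type: distance_angle
      dmin: 0.0
      dmax: 3.8
      amin: 110
      amax: 180
      anchors: [R1, R2, L1]
  - name: halogen_multipolar
    # orthogonal halogen...carbonyl multipolar contact
    receptor_smarts: "[CX3]=[OX1]"
    ligand_smarts: "[Cl,Br,I]"
    criterion:
      type: distance
      dmin: 0.0
      dmax: 3.6
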