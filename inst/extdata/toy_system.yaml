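# Toy binding-site system: illustrative parameters, not fitted.
# Units: nm, kJ/mol, elementary charge, g/mol.
#
# The water-like particle carries no net charge; its hydrogen-bonding
# affinity for polar donors is lumped into an effective LJ well depth.
# Ions carry a large implicit-solvation offset that is active only in
# solvent-like environments (solvation_scale = 1), giving them the
# desolvation penalty they would pay on entering a dehydrated pore.
species:
  water:
    charge: 0.0
    lj_epsilon: 16.0
    lj_sigma: 0.30
    mass: 18.015
    solvation: -10.0
  fluoride:
    charge: -1.0
    lj_epsilon: 0.8
    lj_sigma: 0.37
    mass: 19.0
    solvation: -60.0
  sodium:
    charge: 1.0
    lj_epsilon: 0.3
    lj_sigma: 0.22
    mass: 23.0
    solvation: -45.0

sites:
  # 3-donor pocket: polar donors with small positive partial charges at
  # 0.31 nm from the site center (trigonal), a dehydrated environment.
  f_site:
    centers:
      - {x: 0.310, "y": 0.0000, z: 0.0, charge: 0.01, lj_epsilon: 8.0, lj_sigma: 0.25}
      - {x: -0.155, "y": 0.2685, z: 0.0, charge: 0.01, lj_epsilon: 8.0, lj_sigma: 0.25}
      - {x: -0.155, "y": -0.2685, z: 0.0, charge: 0.01, lj_epsilon: 8.0, lj_sigma: 0.25}
    dielectric: 2.0
    cage_k: 0.0
    escape_radius: 0.6
    box_halfwidth: 0.9
    solvation_scale: 0.0
  # Tetrahedral 4-dipole cage: carbonyl-like centers with small negative
  # partial charges, attractive for a cation.
  tm3_site:
    centers:
      - {x: 0.1559, "y": 0.1559, z: 0.1559, charge: -0.05, lj_epsilon: 2.0, lj_sigma: 0.28}
      - {x: 0.1559, "y": -0.1559, z: -0.1559, charge: -0.05, lj_epsilon: 2.0, lj_sigma: 0.28}
      - {x: -0.1559, "y": 0.1559, z: -0.1559, charge: -0.05, lj_epsilon: 2.0, lj_sigma: 0.28}
      - {x: -0.1559, "y": -0.1559, z: 0.1559, charge: -0.05, lj_epsilon: 2.0, lj_sigma: 0.28}
    dielectric: 2.0
    cage_k: 0.0
    escape_radius: 0.6
    box_halfwidth: 0.9
    solvation_scale: 0.0
  # Featureless solvated box standing in for bulk solvent.
  bulk:
    centers: ~
    dielectric: 1.0
    cage_k: 0.0
    escape_radius: 0.6
    box_halfwidth: 0.9
    solvation_scale: 1.0
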