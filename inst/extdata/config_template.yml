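# flapr run configuration template.
# Every selection threshold is stated here explicitly; nothing is hidden.

# scaffold inputs: PDB paths and/or generated fixtures
scaffolds: []            # e.g. [scaffolds/sca8.pdb]
fixtures:                # generated synthetic scaffolds
  - kind: clamped_hairpin
    id: clamp
  - kind: helix_loop_helix
    id: free

criteria:
  sasa_min: 15           # A^2; every site residue must exceed this (strict >)
  rmsf_constrained: 1.5  # A; "constrained" site bound, also the GA rule bound
  rmsf_csa: 1.0          # A; constrained-and-solvent-accessible (CSA) bound
  mode: windowed         # strict | windowed
  flank_reach: 2         # loop residues allowed between window end and flank

backend:
  type: enm              # enm | ensemble
  cutoff: 7.5            # A, C-alpha contact cutoff of the network model
  temperature: 300       # K
  calibration_target: 0.8  # A; median C-alpha RMSF of the reference fixture
  # calibration_ref: path/to/reference.pdb   # default: the fixture hairpin

energy:
  cutoff: 12             # A, nonbonded truncation
  dielectric_factor: 4   # eps(r) = 4 r
  burial: false
  relax: none            # none | sd

# CDR extraction (extract-cdr): complex + chain roles + CDR ranges
# complex: complexes/fv_antigen.pdb
# receptor_chains: [A]
# ligand_chains: [H, L]
# chain_prefix: {H: TH, L: TL}
# cdr:
#   - {chain: H, name: CDR-H1, start: 26, end: 35}
#   - {chain: H, name: CDR-H2, start: 50, end: 65}
#   - {chain: H, name: CDR-H3, start: 95, end: 102}

selection:
  top_k: 3               # rank mode: top-k windows by binding-energy loss
  # threshold: 23        # threshold mode: minimum loss (model energy units)

# design: peptides to graft (name + 6-letter sequence)
peptides:
  - {name: TH3, seq: SRWGGD}

seed: 1
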