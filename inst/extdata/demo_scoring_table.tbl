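# Synthetic demonstration scoring table (not derived from structural
# statistics). Format: 'bins:' gives strictly increasing upper bin edges
# in Angstrom (last edge = interaction cutoff); rows are
#   RESNAME ATOMNAME RESNAME ATOMNAME bin_index energy
# entries are symmetrized on load; missing combinations default to 0.
name: demo-synthetic
bins: 2.5 5.0 8.0
ALA CA ALA CA 1 8.0
ALA CA ALA CA 2 -1.2
ALA CA ALA CA 3 -0.3
ALA CA GLY CA 1 8.0
ALA CA GLY CA 2 -0.8
ALA CA GLY CA 3 -0.2
ALA CB GLY CA 2 -0.5
GLY CA GLY CA 1 8.0
GLY CA GLY CA 2 -1.0
LEU CB ALA CB 2 -1.5
LEU CB ALA CB 3 -0.4
LEU CA ALA CA 2 -0.9
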