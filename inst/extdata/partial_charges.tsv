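resname	atom	charge	note
*	N	-0.35	backbone amide dipole
*	CA	0.35	backbone amide dipole compensation
*	C	0.45	backbone carbonyl dipole
*	O	-0.45	backbone carbonyl dipole
ASP	OD1	-0.5	carboxylate, charge -1 split
ASP	OD2	-0.5	carboxylate, charge -1 split
GLU	OE1	-0.5	carboxylate, charge -1 split
GLU	OE2	-0.5	carboxylate, charge -1 split
LYS	NZ	1.0	ammonium
ARG	NH1	0.5	guanidinium, charge +1 split
ARG	NH2	0.5	guanidinium, charge +1 split
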