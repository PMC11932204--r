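# Turner 2004 nearest-neighbor helix stacking free energies, kcal/mol, 37 C.
# A row gives dG37 for the 5'->3' step  5'-X1 X2-3' / 3'-Y1 Y2-5'  where
# pair1 = X1:Y1 and pair2 = X2:Y2 (canonical pairs incl. GU wobble).
# The table is symmetric under 180-degree rotation:
# dG(p1, p2) == dG(rev(p2), rev(p1)).
pair1	pair2	dg37
AU	AU	-0.93
AU	CG	-2.24
AU	GC	-2.08
AU	GU	-0.60
AU	UA	-1.10
AU	UG	-1.40
CG	AU	-2.11
CG	CG	-3.26
CG	GC	-2.36
CG	GU	-1.41
CG	UA	-2.08
CG	UG	-2.11
GC	AU	-2.35
GC	CG	-3.42
GC	GC	-3.26
GC	GU	-1.53
GC	UA	-2.24
GC	UG	-2.51
GU	AU	-1.30
GU	CG	-2.51
GU	GC	-2.11
GU	GU	-0.50
GU	UA	-1.40
GU	UG	1.30
UA	AU	-1.33
UA	CG	-2.35
UA	GC	-2.11
UA	GU	-1.00
UA	UA	-0.93
UA	UG	-1.30
UG	AU	-1.00
UG	CG	-1.53
UG	GC	-1.41
UG	GU	0.30
UG	UA	-0.60
UG	UG	-0.50
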