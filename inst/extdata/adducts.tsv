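# Adduct registry: cation formation from a neutral molecule M.
# atoms_added is a Hill formula string (empty = none);
# hydrogens_removed counts neutral H atoms removed; charge is the cation charge.
# Cu/Au entries are screening hypotheses, not confirmed assignments.
name	atoms_added	hydrogens_removed	charge
[M+H]+	H	0	1
[M+Na]+	Na	0	1
[M+2H]2+	H2	0	2
[M-2H+Fe]+	Fe	2	1
[M-H+Cu]+	Cu	1	1
[M-2H+Cu+H2O]+	CuH2O	2	1
[M-2H+Au]+	Au	2	1
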