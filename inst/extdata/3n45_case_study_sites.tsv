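# Ubiquitination sites reported in the literature on human farnesyl
# pyrophosphate synthase (PDB entry 3N45, chain A): five lysines with
# distinct functional contexts (substrate pocket / Mg2+ cofactor,
# allosteric pocket, packed core near folding hotspots, dimer interface,
# KEN degradation motif).
chain_id	res_number	aa	label
A	332	K	Ub
A	123	K	Ub
A	112	K	Ub
A	210	K	Ub
A	352	K	Ub
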