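accession	compartment
PF00051	extracellular
PF01822	extracellular
PF00008	extracellular
PF00041	extracellular
PF00084	extracellular
PF00057	extracellular
PF00059	extracellular
PF01392	extracellular
PF00431	extracellular
PF00090	extracellular
PF02210	extracellular
PF07679	extracellular
PF00017	cytoplasmic
PF00018	cytoplasmic
PF00168	cytoplasmic
PF00169	cytoplasmic
PF00615	cytoplasmic
PF00620	cytoplasmic
PF00621	cytoplasmic
PF00640	cytoplasmic
PF00786	cytoplasmic
PF00788	cytoplasmic
PF02185	cytoplasmic
PF00611	cytoplasmic
PF00046	nuclear
PF00010	nuclear
PF00170	nuclear
PF00249	nuclear
PF00250	nuclear
PF00319	nuclear
PF00320	nuclear
PF00505	nuclear
PF00157	nuclear
PF02864	nuclear
PF00104	nuclear
PF00907	nuclear
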