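# Demo architecture registry: one known architecture per line,
# comma-separated Pfam accessions in N-to-C order. Illustrative only.
PF00051
PF01822
PF00017
PF00018
PF00046
PF00249
PF00059
PF00041
PF00041,PF00017
PF00051,PF01822
PF00051,PF00017
PF00051,PF00046
PF00008,PF00041
PF00046,PF00249
PF00051,PF00051,PF01822
PF00084,PF00084,PF00057
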