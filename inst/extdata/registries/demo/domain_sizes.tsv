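accession	reference_length	length_sd	source_n
PF00051	80	6	120
PF01822	92	8	45
PF00041	85	7	300
PF00059	110	10	85
PF00084	60	5	150
PF00008	38	NA	NA
PF00090	55	4	60
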