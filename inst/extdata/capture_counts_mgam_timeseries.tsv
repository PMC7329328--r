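level	n_inoculum	n_detected_droplets	n_inoculum_detected	n_grew_droplets	n_inoculum_grew
Phylum	4	5	4	5	4
Class	10	11	10	7	5
Order	10	14	10	8	5
Family	17	21	16	13	7
Genus	56	53	40	20	13
SV	89	94	68	34	22
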