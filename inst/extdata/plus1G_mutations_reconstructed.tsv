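gene	exon	exon_start3	psi	source_note
LPL	5	TAA	100	no effect on inclusion; +2/+3 context stated as lacking C/G in the re-analysis; flanking bases reconstructed
HEXA	13	AAA	100	+1G>A change; no effect on inclusion; flanking bases reconstructed
LAMA2	24	TAG	100	+3G stated; other bases reconstructed
NEU1	2	TTG	100	+3G stated; other bases reconstructed
COL6A2	8	TAT	100	no effect on inclusion; flanking bases reconstructed
COL1A1	23	TTA	100	no effect on inclusion; flanking bases reconstructed
PKHD1	25	TCG	99	+1G>T activates cryptic 3'ss; +2C and +3G both stated; PSI counted as inclusion of the longer exon
CAPN3	10	TCA	91	+2C stated; highest PSI of the variable group
GH1	3	TCA	100	+2C stated; printed as 100 in the re-analysis (mutant series in the primary source)
FECH	9	TCT	100	+2C stated; printed as 100 in the re-analysis (mutant series in the primary source)
CLCN2	19	TAT	NA	individual PSI not printed; placeholder pending primary source
EYA1	10	TTA	NA	individual PSI not printed; placeholder pending primary source
COL1A2	37	TAA	NA	individual PSI not printed; placeholder pending primary source
CAPN3	17	TAA	0	complete exon skipping; lowest PSI of the variable group
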