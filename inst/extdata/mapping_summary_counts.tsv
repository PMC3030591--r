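metric	library_1	library_2
raw	92718536	55464728
high_quality	84591386	47744976
35bp	13042363	10522399
30bp	12925983	9316993
25bp	11996273	7171812
unique	4726191	6102251
multiple	33238428	20908953
annotated	37964619	27011204
unique_exon	3608762	5099313
unique_intron	759012	398644
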