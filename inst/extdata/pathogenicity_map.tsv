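raw_label	standardized_code
pathogenic	P
pathogenic variant	P
definitely pathogenic	P
likely pathogenic	LP
probably pathogenic	LP
probable pathogenic	LP
pathogenic, low penetrance	LP
uncertain significance	VUS
variant of uncertain significance	VUS
variant of unknown significance	VUS
uncertain	VUS
unknown	VUS
unknown significance	VUS
unclassified	VUS
vus	VUS
likely benign	LB
probably benign	LB
probably not pathogenic	LB
probable non pathogenic	LB
benign	B
non pathogenic	B
not pathogenic	B
no known pathogenicity	B
neutral	B
polymorphism	B
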