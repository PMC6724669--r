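# ACMG/AMP combining rules for the five-tier classification.
# One row per rule; a row fires when the tag-set counts meet every minimum.
# Columns: outcome, then minimum counts of very-strong (pvs), strong (ps),
# moderate (pm), supporting (pp), stand-alone benign (ba), strong benign (bs),
# supporting benign (bp) tags. P/LP rows are pathogenic-side, B/LB benign-side;
# when both sides fire the classification is VUS.
outcome	pvs	ps	pm	pp	ba	bs	bp
P	1	1	0	0	0	0	0
P	1	0	2	0	0	0	0
P	1	0	1	1	0	0	0
P	1	0	0	2	0	0	0
P	0	2	0	0	0	0	0
P	0	1	3	0	0	0	0
P	0	1	2	2	0	0	0
P	0	1	1	4	0	0	0
LP	1	0	1	0	0	0	0
LP	0	1	1	0	0	0	0
LP	0	1	0	2	0	0	0
LP	0	0	3	0	0	0	0
LP	0	0	2	2	0	0	0
LP	0	0	1	4	0	0	0
B	0	0	0	0	1	0	0
B	0	0	0	0	0	2	0
LB	0	0	0	0	0	1	1
LB	0	0	0	0	0	0	2
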