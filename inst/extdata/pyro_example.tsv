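sample	rsid	level	replicate	allele_a_percent
HAS6	rs149698	DNA	d1	49.8
HAS6	rs149698	DNA	d2	50.6
HAS6	rs149698	DNA	d3	50.1
HAS6	rs149698	RNA	r1	63.5
HAS6	rs149698	RNA	r2	64.4
HAS6	rs149698	RNA	r3	64.0
HAS6	rs149698	RNA	r4	64.5
HAS13	rs149698	DNA	d1	50.9
HAS13	rs149698	DNA	d2	49.4
HAS13	rs149698	DNA	d3	50.3
HAS13	rs149698	RNA	r1	64.8
HAS13	rs149698	RNA	r2	63.6
HAS13	rs149698	RNA	r3	64.2
HAS13	rs149698	RNA	r4	63.9
HAS2	rs149698	DNA	d1	50.2
HAS2	rs149698	DNA	d2	49.6
HAS2	rs149698	DNA	d3	50.8
HAS2	rs149698	RNA	r1	51.3
HAS2	rs149698	RNA	r2	49.9
HAS2	rs149698	RNA	r3	50.6
HAS2	rs149698	RNA	r4	50.1
HAS9	rs149698	DNA	d1	66.2
HAS9	rs149698	DNA	d2	65.1
HAS9	rs149698	DNA	d3	66.8
HAS9	rs149698	RNA	r1	81.0
HAS9	rs149698	RNA	r2	79.4
HAS9	rs149698	RNA	r3	80.2
HAS9	rs149698	RNA	r4	80.6
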