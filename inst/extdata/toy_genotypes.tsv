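rsid	P1	P2	P3
rs12506899	0	1	2
rs2251844	1	1	0
rs17271883	2	0	1
rs3760775	0	0	2
rs265548	1	0	0
rs1047781	0	2	1
rs8176749	0	1	0
rs8176720	1	0	2
rs3670775	0	1	0
rs441810	NA	0	1
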