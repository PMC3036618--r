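gene_id	n_reagents	n_scoring	n_nonscoring	category	expressed
Abl	4	4	0	1	yes
CycA	3	3	0	1	yes
dome	3	3	0	1	yes
hop	3	3	0	1	yes
mts	2	2	0	1	yes
CycE	3	2	1	2	yes
Pp4-19C	4	2	2	2	yes
CG17090	3	2	1	2	yes
puc	3	2	1	2	yes
CG34318|CG8179	4	1	3	3	no
CanA1	3	1	2	3	no
CG4839	3	1	2	3	no
CG7597	3	1	2	3	yes
CG9389	3	1	2	3	no
mtm	3	1	2	3	yes
Pi3K21B	3	1	2	3	yes
smi35A	3	1	2	3	yes
Src42A	3	1	2	3	yes
CG8509	2	1	1	3	no
gskt	2	1	1	3	no
htl	2	1	1	3	no
Myt1	2	1	1	3	yes
Pp1-Y2	2	1	1	3	no
S6k	2	1	1	3	yes
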