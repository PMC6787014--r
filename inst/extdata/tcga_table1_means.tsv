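gene	category	lgg_mean_log2_fpkm	lgg_sd	hgg_mean_log2_fpkm	hgg_sd	printed_fold_change
CXCL10	chemo_attractant	4.7	2.4	8.6	2.0	0.6
CXCL11	chemo_attractant	3.6	2.0	6.4	2.1	0.6
CXCL9	chemo_attractant	4.5	2.2	7.0	1.9	0.7
CCL5	chemo_attractant	6.1	1.8	7.6	1.2	0.8
CCL2	chemo_attractant	8.9	2.0	10.6	1.7	0.8
CCL3	chemo_attractant	9.1	2.4	7.6	1.9	1.2
CCL7	chemo_attractant	0.3	1.1	1.6	2.2	0.2
CCL4	chemo_attractant	8.4	2.5	7.2	1.7	1.2
CCL1	chemo_attractant	0.4	1.0	0.1	0.4	5.3
CXCL3	chemo_attractant	4.7	1.7	5.4	2.3	0.9
CXCL4	chemo_attractant	1.6	1.6	1.5	1.6	1.1
ANXA2	adhesion_motility	10.6	1.1	13.1	1.0	0.8
LGALS1	adhesion_motility	11.5	0.9	13.4	0.9	0.9
LGALS3	adhesion_motility	9.7	0.9	12.3	1.4	0.8
TSPAN24	adhesion_motility	11.6	0.6	13.0	0.9	0.9
ANXA5	adhesion_motility	13.3	0.7	14.6	0.9	0.9
TSPAN30	adhesion_motility	13.9	0.5	15.0	0.8	0.9
ICAM1	adhesion_motility	9.2	1.3	10.5	1.3	0.9
PECAM1	adhesion_motility	9.7	0.8	10.4	0.7	0.9
ITGB2	adhesion_motility	11.5	1.4	12.3	1.1	0.9
TSPAN10	adhesion_motility	3.7	1.5	4.3	1.5	0.9
ITGAL	adhesion_motility	8.2	1.6	8.7	1.3	0.9
TSPAN28	adhesion_motility	15.3	0.6	15.1	0.7	1.0
VCAM1	adhesion_motility	10.7	2.0	11.1	1.4	1.0
ICAM2	adhesion_motility	9.0	0.7	8.8	0.8	1.0
ICOS	cd8_t_cell	1.0	1.5	2.4	1.7	0.4
GZMK	cd8_t_cell	2.5	2.1	4.3	2.1	0.6
CD8A	cd8_t_cell	5.1	1.6	6.2	1.4	0.8
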