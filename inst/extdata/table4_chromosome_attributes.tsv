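# Chromosome-level attributes of the 11 main reference-genome scaffolds.
# Units: scaffold_mb in megabases; gc_percent in %; gene_density = genes/Mbp;
# te_density = transposable elements/Mbp; tandem_dup_prop = proportion of annotated
# genes that are tandem duplicates; diversity_hhw = expected heterozygosity (H_Hw)
# pooled over six species; divergence_fst = F_st between the six species;
# mean_rr = cM/Mb averaged over the 10 mapping parents.
chromosome	mean_rr	scaffold_mb	gc_percent	gene_density	te_density	tandem_dup_prop	diversity_hhw	divergence_fst
1	3.68	40.30	38.0	63.55	401.86	0.088	0.181	0.400
2	2.97	64.24	36.4	53.05	392.64	0.092	0.206	0.376
3	2.16	80.09	35.7	42.84	416.24	0.103	0.229	0.354
4	2.77	41.98	37.2	53.03	430.05	0.085	0.188	0.395
5	1.98	74.73	35.3	44.35	418.50	0.100	0.215	0.359
6	3.66	53.89	37.7	71.49	361.55	0.077	0.175	0.400
7	2.74	52.45	36.8	52.70	412.18	0.092	0.219	0.373
8	2.69	74.33	37.5	56.09	439.17	0.090	0.189	0.383
9	3.01	39.02	37.5	61.00	398.21	0.096	0.194	0.391
10	3.81	39.36	38.3	69.77	406.39	0.090	0.188	0.405
11	3.27	45.51	37.7	67.35	389.91	0.088	0.165	0.403
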