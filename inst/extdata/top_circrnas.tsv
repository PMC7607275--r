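circRNA	alias	chrom	p_value	fc_abs	regulation	circRNA_type	gene_symbol	MRE1	MRE2	MRE3	MRE4	MRE5
hsa_circRNA_103670	hsa_circ_0006168	chr4	0.000005335	66.9668	Up	Exonic	CNOT6L	Hsa-miR-570-5p	Hsa-miR-592	Hsa-miR-542-3p	Hsa-miR-628-5p	Hsa-miR-148b-5p
hsa_circRNA_101833	hsa_circ_0039908	chr16	0.000193084	14.1092	Up	Exonic	DUS2	Hsa-miR-590-5p	Hsa-miR-21-5p	Hsa-miR-654-3p	Hsa-miR-640	Hsa-miR-572
hsa_circRNA_103809	hsa_circ_0072088	chr5	0.000178409	13.6281	Up	Exonic	ZFR	Hsa-miR-511-5p	Hsa-miR-130b-5p	Hsa-miR-642a-5p	Hsa-miR-532-3p	Hsa-miR-329-5p
hsa_circRNA_104855	hsa_circ_0087888	chr9	0.013291027	12.7997	Up	Exonic	TMEM245	Hsa-miR-567	Hsa-miR-183-5p	Hsa-miR-652-3p	Hsa-let-7f-1-3p	Hsa-miR-338-5p
hsa_circRNA_104761	hsa_circ_0001847	chr9	0.001438757	11.1789	Up	Exonic	UBAP2	Hsa-miR-34c-5p	Hsa-miR-449a	Hsa-miR-449b-5p	Hsa-miR-449c-5p	Hsa-miR-370-3p
hsa_circRNA_102610	hsa_circ_0000972	chr2	0.006983514	9.7333	Up	Exonic	MBOAT2	Hsa-miR-330-3p	Hsa-miR-130b-3p	Hsa-miR-130a-3p	Hsa-miR-513a-3p	Hsa-miR-136-5p
hsa_circRNA_103444	hsa_circ_0008797	chr3	0.048378398	8.4084	Up	Exonic	GSK3B	Hsa-miR-508-5p	Hsa-miR-500a-5p	Hsa-miR-7-5p	Hsa-miR-29a-5p	Hsa-miR-623
hsa_circRNA_100257	hsa_circ_0002454	chr1	0.008199393	8.4059	Up	Exonic	DNAJC6	Hsa-miR-508-3p	Hsa-miR-542-3p	Hsa-miR-516b-5p	Hsa-miR-518e-5p	Hsa-miR-519b-5p
hsa_circRNA_103149	hsa_circ_0002903	chr21	0.004270572	7.7418	Up	Exonic	PCNT	Hsa-miR-29b-1-5p	Hsa-miR-329-5p	Hsa-miR-136-5p	Hsa-miR-1264	Hsa-miR-26b-3p
hsa_circRNA_100983	hsa_circ_0024766	chr11	0.026330597	7.2345	Up	Exonic	STT3A	Hsa-miR-376a-2-5p	Hsa-miR-873-5p	Hsa-miR-765	Hsa-miR-576-3p	Hsa-miR-423-3p
hsa_circRNA_000367	hsa_circ_0000367	chr11	0.000764274	15.1939	Down	Exonic	SIAE	Hsa-miR-331-3p	Hsa-miR-4646-5p	Hsa-miR-4797-5p	Hsa-miR-3919	Hsa-miR-3190-3p
hsa_circRNA_100236	hsa_circ_0012634	chr1	0.000005729	6.6553	Down	Exonic	TMEM59	Hsa-miR-508-5p	Hsa-miR-372-5p	Hsa-miR-655-5p	Hsa-miR-519d-5p	Hsa-miR-668-3p
hsa_circRNA_100790	hsa_circ_0000288	chr11	0.005757781	5.7756	Down	Exonic	CAPRIN1	Hsa-miR-20b-3p	Hsa-miR-150-3p	Hsa-miR-133a-5p	Hsa-miR-509-3p	Hsa-miR-485-5p
hsa_circRNA_100789	hsa_circ_0021652	chr11	0.004277333	5.6822	Down	Exonic	CAPRIN1	Hsa-miR-873-5p	Hsa-miR-20b-3p	Hsa-miR-649	Hsa-miR-150-3p	Hsa-miR-133a-5p
hsa_circRNA_102413	hsa_circ_0003745	chr19	0.000034324	5.4179	Down	Exonic	PIP5K1C	Hsa-miR-432-5p	Hsa-miR-138-5p	Hsa-miR-1264	Hsa-miR-658	Hsa-miR-873-5p
hsa_circRNA_103689	hsa_circ_0007324	chr4	0.000103109	4.3421	Down	Exonic	PTPN13	Hsa-miR-548d-3p	Hsa-miR-489-3p	Hsa-miR-145-5p	Hsa-miR-29a-5p	Hsa-miR-520g-5p
hsa_circRNA_101784	hsa_circ_0008223	chr16	0.000159064	4.1580	Down	Exonic	XPO6	Hsa-miR-106b-3p	Hsa-miR-500a-3p	Hsa-miR-412-3p	Hsa-miR-222-5p	Hsa-miR-638
hsa_circRNA_104950	hsa_circ_0089252	chr9	0.000552165	3.7261	Down	Exonic	RAPGEF1	Hsa-miR-766-3p	Hsa-miR-367-5p	Hsa-miR-9-5p	Hsa-miR-770-5p	Hsa-miR-504-5p
hsa_circRNA_103846	hsa_circ_0002512	chr5	0.000293167	3.6087	Down	Exonic	DEPDC1B	Hsa-miR-607	Hsa-miR-589-3p	Hsa-miR-605-5p	Hsa-miR-550a-5p	Hsa-miR-550a-3-5p
hsa_circRNA_101698	hsa_circ_0000669	chr16	0.000556995	3.3769	Down	Exonic	CARHSP1	Hsa-miR-185-3p	Hsa-miR-146b-3p	Hsa-miR-298	Hsa-miR-128-2-5p	Hsa-miR-92a-2-5p
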