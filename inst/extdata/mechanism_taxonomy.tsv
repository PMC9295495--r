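region_class	mechanism	vep_categories	predictor_class	exemplar
promoter	tf_binding_alteration	upstream_gene_variant,regulatory_region_variant,TF_binding_site_variant	tf_motif_disruption	GATA1:-113A>G hereditary persistence of foetal haemoglobin
promoter	transcription_alteration	upstream_gene_variant,5_prime_UTR_variant	none_established	CHM c.-98C>A choroideremia
promoter	methylation_alteration	upstream_gene_variant,5_prime_UTR_variant	none_established	BRCA1:c.-107A>T breast/ovarian cancer
five_prime_utr	uAUG_creation	5_prime_UTR_variant	utr_annotation	NF1:c.-272G>A neurofibromatosis type 1
five_prime_utr	uORF_perturbation	5_prime_UTR_variant	utr_annotation	NF2:-66-65insT neurofibromatosis type 2
five_prime_utr	IRES_disruption	5_prime_UTR_variant	ires_prediction	GJB1:c.-103C>T Charcot-Marie-Tooth disease
five_prime_utr	utr_splice_disruption	5_prime_UTR_variant,splice_region_variant	splicing_prediction	SHOX:c.-19G>A SHOX haploinsufficiency
five_prime_utr	kozak_alteration	5_prime_UTR_variant	utr_annotation	GATA4:c.-6G>C atrial septal defect
five_prime_utr	n_terminal_elongation	5_prime_UTR_variant	utr_annotation	MEF2C:c.-8C>T developmental disorder
intron	canonical_splice_disruption	splice_donor_variant,splice_acceptor_variant,splice_region_variant,splice_donor_5th_base_variant,splice_polypyrimidine_tract_variant	splicing_prediction	MYBPC3:c.3490+1G>A hypertrophic cardiomyopathy
intron	branchpoint	intron_variant	splicing_prediction	HNF4A:c.264-21A>G maturity-onset diabetes of the young
intron	pseudo_exon_activation	intron_variant	splicing_prediction	DMD:c.7310-19A>G muscular dystrophy
intron	poison_exon_inclusion	intron_variant	splicing_prediction	SCN1A:c.4002+2165C>T Dravet syndrome
intron	splice_motif_spacing	intron_variant	splicing_prediction	DOK7:c.54+8_54+17del congenital myasthenia
intron	cryptic_exon_activation	intron_variant	splicing_prediction	VHL deep intronic erythrocytosis
three_prime_utr	polyA_signal_disruption	3_prime_UTR_variant	polya_motif	NAA10:c.*43A>G microphthalmia
three_prime_utr	miRNA_site_disruption	3_prime_UTR_variant	mirna_target	REEP1 hereditary spastic paraplegia
three_prime_utr	utr3_splice_disruption	3_prime_UTR_variant,splice_region_variant	splicing_prediction	LHFPL5:c.*16+1G>A hearing impairment
cre	tf_binding_alteration	regulatory_region_variant,TF_binding_site_variant,TFBS_ablation,intergenic_variant	tf_motif_disruption	SHH regulatory region holoprosencephaly
cre	enhancer_disruption	regulatory_region_variant,regulatory_region_ablation	none_established	PTF1A enhancer isolated pancreatic agenesis
other	new_regulatory_element	intergenic_variant,upstream_gene_variant,downstream_gene_variant	none_established	alpha-globin locus gained promoter alpha-thalassaemia
other	mirna_seed	mature_miRNA_variant,non_coding_transcript_exon_variant	mirna_target	miR-204:n.37C>T retinal dystrophy
other	snrna_structure	non_coding_transcript_exon_variant	none_established	RNU12 cerebellar ataxia
other	snrna_splicing	non_coding_transcript_variant	splicing_prediction	RNU4ATAC Roifman syndrome
other	snorna_expression	non_coding_transcript_variant	none_established	SNORD118 leukoencephalopathy
other	tad_boundary_disruption	intergenic_variant	none_established	EPHA4 locus limb malformations
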