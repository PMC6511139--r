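# Consequence-term -> impact map used for the annotation category schemes.
# upstream_gene_variant / downstream_gene_variant are classed LOW here
# (stock VEP calls them MODIFIER); edit a copy of this file and pass it to
# vep_impact_map() to restore stock semantics.
HIGH:
  - stop_gained
  - stop_lost
  - start_lost
  - frameshift_variant
  - splice_acceptor_variant
  - splice_donor_variant
  - transcript_ablation
MODERATE:
  - missense_variant
  - inframe_insertion
  - inframe_deletion
  - protein_altering_variant
LOW:
  - synonymous_variant
  - stop_retained_variant
  - start_retained_variant
  - splice_region_variant
  - upstream_gene_variant
  - downstream_gene_variant
  - incomplete_terminal_codon_variant
MODIFIER:
  - intron_variant
  - intergenic_variant
  - 3_prime_UTR_variant
  - 5_prime_UTR_variant
  - non_coding_transcript_variant
  - non_coding_transcript_exon_variant
  - regulatory_region_variant
  - TF_binding_site_variant
  - mature_miRNA_variant
  - coding_sequence_variant
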