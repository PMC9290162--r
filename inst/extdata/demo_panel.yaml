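# Demonstration BCR-ABL1-style screening panel.
#
# The isoform sequences below are SYNTHETIC stand-ins engineered so that
# every catalogued mutation is representable at its stated codon; they are
# not the true BCR-ABL1 fusion transcript. The 'e13a2' isoform equals
# 'e14a2' with an internal 74-base block of the 5' (fusion-partner) region
# removed, mimicking alternative exon usage upstream of the kinase domain.
# Real deployments replace the sequences (inline or via a 'fasta' path per
# isoform) and keep the codon-numbering metadata accurate.
name: demo-bcr-abl1
forward_primer: TTCAGGAGTATAGAGTCTCTCC
reverse_primer: TTCCCGGTTAAATGGGATGATC
max_primer_mismatches: 2
positive_cutoff: 0.005   # fraction; >= is positive
clinical_cutoff: 0.01    # fraction; > is clinically reportable
min_coverage: 100
min_alt_reads: 3
isoforms:
  - isoform_id: e14a2
    cds_start: 121
    codon_offset: 244
    description: synthetic stand-in, dominant isoform
    sequence: AGTTCTTCGTAGTCAAGATGCTAGCGTATATGTACTAATCTGTTTCTCGGACCACCTACGCTAGTGACGAATTGTCGCGGCAGTAGTCCGTTTAGCCCCTATTGGGAGCGTCTTCGGCATATGATTGTTAAATCTACGATAAGCTGCTATGCTGAAGCAAGCGTTTGGTTGAATAGTGCCAGACAGGAGTTCATTGGGGCCATGCGACTGGAAGAAGATGTATTATGCAGACTTAAAAGTACACGCTGCGTCAATTGCTTAACAGTGCGTCGACAGCGACGTCTGAATGTACTCGACACGTCATTTCCCTTAGATTTGAGTTAATAGCTACGGACTGGGTTCATTCGCCGATCTGAAGGTTCTAACTGTCGACTACAGCTTCTTTGGACTGGATGGTGAAAGTATGTTTTACCGCATAACACTTCTGCCTACACTGGACACTTAGCCTAAGCCGGTACCGCCCGATTTCAATCTGAAATTCAAGGGGAGGACAAGCGCAGACGGTGCTTCTGTACTTTTTTCCCAAGGCGTTCCGCTTGGATGGGGATGTTGAGGCTTATCGACAAGCACAGGTGTCATTGGACGGAGTTGAGGCCCAGTTATTATAACTTCTAATACTCGGGTAAACATGTGGAAAGACATTTGCGCTAGGCGGCTTGCTAGCATTGGGTTCTTGAGCTACGCTCCCTCGTCCTCGCCCCGAAAGAACCGGTATGTGCGACTTCCGAAGCGAGCATCGAACCAGGATACACGCGTGACATCGTTTATGTCTCGGTTGATGTCGCGTGTCCTCCTCCGAATACTATGAATGTGGAAAAATTA
  - isoform_id: e13a2
    cds_start: 47
    codon_offset: 244
    description: synthetic stand-in, alternative isoform (internal 74-base deletion)
    sequence: AGTTCTTCGTAGTCAAGATGCTACCTATTGGGAGCGTCTTCGGCATATGATTGTTAAATCTACGATAAGCTGCTATGCTGAAGCAAGCGTTTGGTTGAATAGTGCCAGACAGGAGTTCATTGGGGCCATGCGACTGGAAGAAGATGTATTATGCAGACTTAAAAGTACACGCTGCGTCAATTGCTTAACAGTGCGTCGACAGCGACGTCTGAATGTACTCGACACGTCATTTCCCTTAGATTTGAGTTAATAGCTACGGACTGGGTTCATTCGCCGATCTGAAGGTTCTAACTGTCGACTACAGCTTCTTTGGACTGGATGGTGAAAGTATGTTTTACCGCATAACACTTCTGCCTACACTGGACACTTAGCCTAAGCCGGTACCGCCCGATTTCAATCTGAAATTCAAGGGGAGGACAAGCGCAGACGGTGCTTCTGTACTTTTTTCCCAAGGCGTTCCGCTTGGATGGGGATGTTGAGGCTTATCGACAAGCACAGGTGTCATTGGACGGAGTTGAGGCCCAGTTATTATAACTTCTAATACTCGGGTAAACATGTGGAAAGACATTTGCGCTAGGCGGCTTGCTAGCATTGGGTTCTTGAGCTACGCTCCCTCGTCCTCGCCCCGAAAGAACCGGTATGTGCGACTTCCGAAGCGAGCATCGAACCAGGATACACGCGTGACATCGTTTATGTCTCGGTTGATGTCGCGTGTCCTCCTCCGAATACTATGAATGTGGAAAAATTA
known_mutations: [M244V, K247R, Y253H, E255K, E255V, L273M, D276G, L298V, T315I, F359C, F359I, F359V, H396R, E450G, M472I]
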