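# name: CA20
# mode: ca20
# SYNTHETIC PLACEHOLDER: stand-in ids for the 20-gene centrosome-amplification signature
# Replace with the published gene list before real use.
CA20_GENE_001
CA20_GENE_002
CA20_GENE_003
CA20_GENE_004
CA20_GENE_005
CA20_GENE_006
CA20_GENE_007
CA20_GENE_008
CA20_GENE_009
CA20_GENE_010
CA20_GENE_011
CA20_GENE_012
CA20_GENE_013
CA20_GENE_014
CA20_GENE_015
CA20_GENE_016
CA20_GENE_017
CA20_GENE_018
CA20_GENE_019
CA20_GENE_020
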