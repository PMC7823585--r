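# name: TP53
# mode: mean_z
# Four-gene downstream transcriptomic readout of TP53 pathway disruption;
# consistently up-regulated in TP53-mutated tumors.
CDC20
CENPA
KIF2C
PLK1
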