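# name: proliferation
# mode: mean_z
# SYNTHETIC PLACEHOLDER: stand-in ids for the 110-gene in-vitro proliferation signature
# Replace with the published gene list before real use.
proliferation_GENE_001
proliferation_GENE_002
proliferation_GENE_003
proliferation_GENE_004
proliferation_GENE_005
proliferation_GENE_006
proliferation_GENE_007
proliferation_GENE_008
proliferation_GENE_009
proliferation_GENE_010
proliferation_GENE_011
proliferation_GENE_012
proliferation_GENE_013
proliferation_GENE_014
proliferation_GENE_015
proliferation_GENE_016
proliferation_GENE_017
proliferation_GENE_018
proliferation_GENE_019
proliferation_GENE_020
proliferation_GENE_021
proliferation_GENE_022
proliferation_GENE_023
proliferation_GENE_024
proliferation_GENE_025
proliferation_GENE_026
proliferation_GENE_027
proliferation_GENE_028
proliferation_GENE_029
proliferation_GENE_030
proliferation_GENE_031
proliferation_GENE_032
proliferation_GENE_033
proliferation_GENE_034
proliferation_GENE_035
proliferation_GENE_036
proliferation_GENE_037
proliferation_GENE_038
proliferation_GENE_039
proliferation_GENE_040
proliferation_GENE_041
proliferation_GENE_042
proliferation_GENE_043
proliferation_GENE_044
proliferation_GENE_045
proliferation_GENE_046
proliferation_GENE_047
proliferation_GENE_048
proliferation_GENE_049
proliferation_GENE_050
proliferation_GENE_051
proliferation_GENE_052
proliferation_GENE_053
proliferation_GENE_054
proliferation_GENE_055
proliferation_GENE_056
proliferation_GENE_057
proliferation_GENE_058
proliferation_GENE_059
proliferation_GENE_060
proliferation_GENE_061
proliferation_GENE_062
proliferation_GENE_063
proliferation_GENE_064
proliferation_GENE_065
proliferation_GENE_066
proliferation_GENE_067
proliferation_GENE_068
proliferation_GENE_069
proliferation_GENE_070
proliferation_GENE_071
proliferation_GENE_072
proliferation_GENE_073
proliferation_GENE_074
proliferation_GENE_075
proliferation_GENE_076
proliferation_GENE_077
proliferation_GENE_078
proliferation_GENE_079
proliferation_GENE_080
proliferation_GENE_081
proliferation_GENE_082
proliferation_GENE_083
proliferation_GENE_084
proliferation_GENE_085
proliferation_GENE_086
proliferation_GENE_087
proliferation_GENE_088
proliferation_GENE_089
proliferation_GENE_090
proliferation_GENE_091
proliferation_GENE_092
proliferation_GENE_093
proliferation_GENE_094
proliferation_GENE_095
proliferation_GENE_096
proliferation_GENE_097
proliferation_GENE_098
proliferation_GENE_099
proliferation_GENE_100
proliferation_GENE_101
proliferation_GENE_102
proliferation_GENE_103
proliferation_GENE_104
proliferation_GENE_105
proliferation_GENE_106
proliferation_GENE_107
proliferation_GENE_108
proliferation_GENE_109
proliferation_GENE_110
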