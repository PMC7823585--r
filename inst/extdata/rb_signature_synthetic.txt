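# name: RB
# mode: mean_z
# SYNTHETIC PLACEHOLDER: stand-in ids for the 182-gene retinoblastoma-pathway signature
# Replace with the published gene list before real use.
RB_GENE_001
RB_GENE_002
RB_GENE_003
RB_GENE_004
RB_GENE_005
RB_GENE_006
RB_GENE_007
RB_GENE_008
RB_GENE_009
RB_GENE_010
RB_GENE_011
RB_GENE_012
RB_GENE_013
RB_GENE_014
RB_GENE_015
RB_GENE_016
RB_GENE_017
RB_GENE_018
RB_GENE_019
RB_GENE_020
RB_GENE_021
RB_GENE_022
RB_GENE_023
RB_GENE_024
RB_GENE_025
RB_GENE_026
RB_GENE_027
RB_GENE_028
RB_GENE_029
RB_GENE_030
RB_GENE_031
RB_GENE_032
RB_GENE_033
RB_GENE_034
RB_GENE_035
RB_GENE_036
RB_GENE_037
RB_GENE_038
RB_GENE_039
RB_GENE_040
RB_GENE_041
RB_GENE_042
RB_GENE_043
RB_GENE_044
RB_GENE_045
RB_GENE_046
RB_GENE_047
RB_GENE_048
RB_GENE_049
RB_GENE_050
RB_GENE_051
RB_GENE_052
RB_GENE_053
RB_GENE_054
RB_GENE_055
RB_GENE_056
RB_GENE_057
RB_GENE_058
RB_GENE_059
RB_GENE_060
RB_GENE_061
RB_GENE_062
RB_GENE_063
RB_GENE_064
RB_GENE_065
RB_GENE_066
RB_GENE_067
RB_GENE_068
RB_GENE_069
RB_GENE_070
RB_GENE_071
RB_GENE_072
RB_GENE_073
RB_GENE_074
RB_GENE_075
RB_GENE_076
RB_GENE_077
RB_GENE_078
RB_GENE_079
RB_GENE_080
RB_GENE_081
RB_GENE_082
RB_GENE_083
RB_GENE_084
RB_GENE_085
RB_GENE_086
RB_GENE_087
RB_GENE_088
RB_GENE_089
RB_GENE_090
RB_GENE_091
RB_GENE_092
RB_GENE_093
RB_GENE_094
RB_GENE_095
RB_GENE_096
RB_GENE_097
RB_GENE_098
RB_GENE_099
RB_GENE_100
RB_GENE_101
RB_GENE_102
RB_GENE_103
RB_GENE_104
RB_GENE_105
RB_GENE_106
RB_GENE_107
RB_GENE_108
RB_GENE_109
RB_GENE_110
RB_GENE_111
RB_GENE_112
RB_GENE_113
RB_GENE_114
RB_GENE_115
RB_GENE_116
RB_GENE_117
RB_GENE_118
RB_GENE_119
RB_GENE_120
RB_GENE_121
RB_GENE_122
RB_GENE_123
RB_GENE_124
RB_GENE_125
RB_GENE_126
RB_GENE_127
RB_GENE_128
RB_GENE_129
RB_GENE_130
RB_GENE_131
RB_GENE_132
RB_GENE_133
RB_GENE_134
RB_GENE_135
RB_GENE_136
RB_GENE_137
RB_GENE_138
RB_GENE_139
RB_GENE_140
RB_GENE_141
RB_GENE_142
RB_GENE_143
RB_GENE_144
RB_GENE_145
RB_GENE_146
RB_GENE_147
RB_GENE_148
RB_GENE_149
RB_GENE_150
RB_GENE_151
RB_GENE_152
RB_GENE_153
RB_GENE_154
RB_GENE_155
RB_GENE_156
RB_GENE_157
RB_GENE_158
RB_GENE_159
RB_GENE_160
RB_GENE_161
RB_GENE_162
RB_GENE_163
RB_GENE_164
RB_GENE_165
RB_GENE_166
RB_GENE_167
RB_GENE_168
RB_GENE_169
RB_GENE_170
RB_GENE_171
RB_GENE_172
RB_GENE_173
RB_GENE_174
RB_GENE_175
RB_GENE_176
RB_GENE_177
RB_GENE_178
RB_GENE_179
RB_GENE_180
RB_GENE_181
RB_GENE_182
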