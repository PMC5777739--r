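STROMAL_SYNTHETIC
G0141
G0142
G0143
G0144
G0145
G0146
G0147
G0148
G0149
G0150
G0151
G0152
G0153
G0154
G0155
G0156
G0157
G0158
G0159
G0160
G0161
G0162
G0163
G0164
G0165
G0166
G0167
G0168
G0169
G0170
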