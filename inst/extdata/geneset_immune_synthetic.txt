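IMMUNE_SYNTHETIC
G0171
G0172
G0173
G0174
G0175
G0176
G0177
G0178
G0179
G0180
G0181
G0182
G0183
G0184
G0185
G0186
G0187
G0188
G0189
G0190
G0191
G0192
G0193
G0194
G0195
G0196
G0197
G0198
G0199
G0200
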