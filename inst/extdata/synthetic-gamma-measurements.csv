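"channel","power","count"
"R",0,0
"R",0.05,66
"R",0.1,90
"R",0.15,109
"R",0.2,124
"R",0.25,137
"R",0.3,148
"R",0.35,159
"R",0.4,169
"R",0.45,178
"R",0.5,187
"R",0.55,195
"R",0.6,203
"R",0.65,210
"R",0.7,217
"R",0.75,224
"R",0.8,231
"R",0.85,237
"R",0.9,243
"R",0.95,249
"R",1,255
"G",0,0
"G",0.05,66
"G",0.1,90
"G",0.15,109
"G",0.2,124
"G",0.25,137
"G",0.3,148
"G",0.35,159
"G",0.4,169
"G",0.45,178
"G",0.5,187
"G",0.55,195
"G",0.6,203
"G",0.65,210
"G",0.7,217
"G",0.75,224
"G",0.8,231
"G",0.85,237
"G",0.9,243
"G",0.95,249
"G",1,255
"B",0,0
"B",0.05,66
"B",0.1,90
"B",0.15,109
"B",0.2,124
"B",0.25,137
"B",0.3,148
"B",0.35,159
"B",0.4,169
"B",0.45,178
"B",0.5,187
"B",0.55,195
"B",0.6,203
"B",0.65,210
"B",0.7,217
"B",0.75,224
"B",0.8,231
"B",0.85,237
"B",0.9,243
"B",0.95,249
"B",1,255
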