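"var","Upd1","Upd2","Upd3","Inh1","Inh2","Inh3","Shf1","Shf2","Shf3","G1","G2","G3"
"Upd1",1,0.557,0.552,0,0,0,0,0,0,0.325,0.325,0.317
"Upd2",0.557,1,0.559,0,0,0,0,0,0,0.329,0.329,0.321
"Upd3",0.552,0.559,1,0,0,0,0,0,0,0.326,0.326,0.318
"Inh1",0,0,0,1,0.566,0.571,0,0,0,0.1,0.1,0.098
"Inh2",0,0,0,0.566,1,0.588,0,0,0,0.103,0.103,0.101
"Inh3",0,0,0,0.571,0.588,1,0,0,0,0.104,0.104,0.101
"Shf1",0,0,0,0,0,0,1,0.52,0.558,0.05,0.05,0.049
"Shf2",0,0,0,0,0,0,0.52,1,0.528,0.047,0.047,0.046
"Shf3",0,0,0,0,0,0,0.558,0.528,1,0.051,0.051,0.05
"G1",0.325,0.329,0.326,0.1,0.103,0.104,0.05,0.047,0.051,1,0.628,0.613
"G2",0.325,0.329,0.326,0.1,0.103,0.104,0.05,0.047,0.051,0.628,1,0.613
"G3",0.317,0.321,0.318,0.098,0.101,0.101,0.049,0.046,0.05,0.613,0.613,1
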