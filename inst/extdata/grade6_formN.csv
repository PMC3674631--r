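"","-","+/-","+","++","+++","++++"
"-",225,8,2,2,0,0
"+/-",9,22,5,0,0,0
"+",0,5,25,6,0,0
"++",0,0,2,20,1,0
"+++",0,0,0,1,6,0
"++++",0,0,0,0,0,3
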