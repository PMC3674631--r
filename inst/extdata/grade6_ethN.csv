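"","-","+/-","+","++","+++","++++"
"-",133,1,0,0,0,0
"+/-",24,29,12,0,0,0
"+",0,4,44,11,0,0
"++",0,0,4,34,9,0
"+++",0,0,0,3,16,5
"++++",0,0,0,0,0,13
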