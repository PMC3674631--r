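"","cytoplasmic","nuclear","atypical","negative"
"cytoplasmic",59,0,7,22
"nuclear",0,61,4,0
"atypical",3,10,40,2
"negative",0,0,1,133
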