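"","cytoplasmic","atypical","negative"
"cytoplasmic",91,0,9
"atypical",8,0,0
"negative",9,0,225
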