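role,label,ppm,distance
train,0% NaCl,0,0
train,0.2% NaCl,2000,710105
train,0.4% NaCl,4000,1041017
test,Blind-2,0,84262
test,Blind-1,2000,694212
test,Blind-3,4000,1045317
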