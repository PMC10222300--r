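role,label,ppm,distance
train,0% Bleach,0,0
train,0.2% Bleach,2000,1462551
train,0.4% Bleach,4000,2032496
train,0.6% Bleach,6000,2399584
test,Blind-2,0,96840
test,Blind-3,2000,
test,Blind-4,4000,2026160
test,Blind-1,6000,2403806
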