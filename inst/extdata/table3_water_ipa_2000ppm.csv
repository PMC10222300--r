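role,label,ppm,distance
train,0% Water,0,0
train,0.2% Water,2000,153083
train,0.4% Water,4000,372865
train,0.6% Water,6000,528991
test,Blind-3,0,19475
test,Blind-2,2000,156608
test,Blind-4,4000,384306
test,Blind-1,6000,540378
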