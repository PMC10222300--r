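role,label,ppm,distance
train,0% Water,0,0
train,1% Water,10000,873013
train,2% Water,20000,1917048
train,3% Water,30000,3116386
train,4% Water,40000,4260250
train,5% Water,50000,5598519
test,Blind-2,0,33157
test,Blind-5,10000,864963
test,Blind-6,20000,1910652
test,Blind-3,30000,3086471
test,Blind-1,40000,4250653
test,Blind-4,50000,5556104
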