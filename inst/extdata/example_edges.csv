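source,target
a,b
a,w
a,c
b,u
b,w
u,e
w,c
w,d
e,v
d,v
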