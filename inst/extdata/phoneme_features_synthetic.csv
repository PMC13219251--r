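phoneme,syl,son,cons,cont,delrel,lat,nas,strid,voi,sg,cg,ant,cor,distr,lab,hi,lo,back,rnd,tense,long
b,-,-,+,-,-,-,-,-,+,-,-,+,-,-,+,-,-,-,-,-,-
p,-,-,+,-,-,-,-,-,-,-,-,+,-,-,+,-,-,-,-,-,-
d,-,-,+,-,-,-,-,-,+,-,-,+,+,-,-,-,-,-,-,-,-
t,-,-,+,-,-,-,-,-,-,-,-,+,+,-,-,-,-,-,-,-,-
g,-,-,+,-,-,-,-,-,+,-,-,-,-,-,-,+,-,+,-,-,-
k,-,-,+,-,-,-,-,-,-,-,-,-,-,-,-,+,-,+,-,-,-
m,-,+,+,-,-,-,+,-,+,-,-,+,-,-,+,-,-,-,-,-,-
n,-,+,+,-,-,-,+,-,+,-,-,+,+,-,-,-,-,-,-,-,-
ŋ,-,+,+,-,-,-,+,-,+,-,-,-,-,-,-,+,-,+,-,-,-
l,-,+,+,+,-,+,-,-,+,-,-,+,+,-,-,-,-,-,-,-,-
r,-,+,+,+,-,-,-,-,+,-,-,+,+,-,-,-,-,-,-,-,-
f,-,-,+,+,-,-,-,+,-,-,-,+,-,-,+,-,-,-,-,-,-
v,-,-,+,+,-,-,-,+,+,-,-,+,-,-,+,-,-,-,-,-,-
s,-,-,+,+,-,-,-,+,-,-,-,+,+,-,-,-,-,-,-,-,-
z,-,-,+,+,-,-,-,+,+,-,-,+,+,-,-,-,-,-,-,-,-
ʃ,-,-,+,+,-,-,-,+,-,-,-,-,+,+,-,-,-,-,-,-,-
x,-,-,+,+,-,-,-,-,-,-,-,-,-,-,-,+,-,+,-,-,-
h,-,-,-,+,-,-,-,-,-,+,-,-,-,-,-,-,-,-,-,-,-
j,-,+,-,+,-,-,-,-,+,-,-,-,-,-,-,+,-,-,-,-,-
aː,+,+,-,+,-,-,-,-,+,-,-,-,-,-,-,-,+,-,-,+,+
eː,+,+,-,+,-,-,-,-,+,-,-,-,-,-,-,-,-,-,-,+,+
iː,+,+,-,+,-,-,-,-,+,-,-,-,-,-,-,+,-,-,-,+,+
oː,+,+,-,+,-,-,-,-,+,-,-,-,-,-,-,-,-,+,+,+,+
uː,+,+,-,+,-,-,-,-,+,-,-,-,-,-,-,+,-,+,+,+,+
yː,+,+,-,+,-,-,-,-,+,-,-,-,-,-,+,+,-,-,+,+,+
øː,+,+,-,+,-,-,-,-,+,-,-,-,-,-,+,-,-,-,+,+,+
ɛː,+,+,-,+,-,-,-,-,+,-,-,-,-,-,-,-,-,-,-,-,+
a,+,+,-,+,-,-,-,-,+,-,-,-,-,-,-,-,+,-,-,-,-
ɛ,+,+,-,+,-,-,-,-,+,-,-,-,-,-,-,-,-,-,-,-,-
ɪ,+,+,-,+,-,-,-,-,+,-,-,-,-,-,-,+,-,-,-,-,-
ɔ,+,+,-,+,-,-,-,-,+,-,-,-,-,-,-,-,-,+,+,-,-
ʊ,+,+,-,+,-,-,-,-,+,-,-,-,-,-,-,+,-,+,+,-,-
ts,-,-,+,-,+,-,-,+,-,-,-,+,+,-,-,-,-,-,-,-,-
pf,-,-,+,-,+,-,-,+,-,-,-,+,-,-,+,-,-,-,-,-,-
aɪ,+,+,-,+,-,-,-,-,+,-,-,-,-,-,-,-,+,-,-,+,-
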