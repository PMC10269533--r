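# calibration_factor: 0.95707472178060404
residue	area
A	123.462639109698
C	159.831478537361
D	184.715421303657
E	213.427662957075
F	229.697933227345
G	99.5357710651828
H	214.384737678855
I	188.543720190779
K	225.869634340223
L	192.372019077901
M	214.384737678855
N	186.629570747218
P	152.174880763116
Q	215.341812400636
R	262.238473767886
S	148.346581875994
T	164.616852146264
V	166.531001589825
W	272.766295707472
Y	251.710651828299
X	193.329093799682
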