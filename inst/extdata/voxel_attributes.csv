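aa,hydropathy,isoelectric,charge
A,1.8,6.00,0
C,2.5,5.07,0
D,-3.5,2.77,-1
E,-3.5,3.22,-1
F,2.8,5.48,0
G,-0.4,5.97,0
H,-3.2,7.59,0.1
I,4.5,6.02,0
K,-3.9,9.74,1
L,3.8,5.98,0
M,1.9,5.74,0
N,-3.5,5.41,0
P,-1.6,6.30,0
Q,-3.5,5.65,0
R,-4.5,10.76,1
S,-0.8,5.68,0
T,-0.7,5.60,0
V,4.2,5.96,0
W,-0.9,5.89,0
Y,-1.3,5.66,0
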