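row_label,members,n,tested
I,I,18,TRUE
W,W,16,TRUE
X,X,17,TRUE
R and R0,R;R0,5,FALSE
HV and HV0a,HV;HV0a,10,TRUE
"H, H1, H2, H3 and H4",H;H1;H2;H3;H4,337,TRUE
H,H,150,TRUE
H1,H1,120,TRUE
H2,H2,25,TRUE
H3,H3,32,TRUE
H4,H4,10,TRUE
V,V,19,TRUE
J1 and J2a,J1;J2a,88,TRUE
J1,J1,69,TRUE
J2a,J2a,17,TRUE
"T, T1 and T2",T;T1;T2,85,TRUE
T,T,2,FALSE
T1,T1,19,TRUE
T2,T2,64,TRUE
U and U5,U;U5,104,TRUE
U,U,42,TRUE
U5,U5,61,TRUE
K,K,56,TRUE
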