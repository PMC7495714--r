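row_label,members,n,tested
I,I,1,FALSE
W,W,3,FALSE
X,X,4,FALSE
R and R0,R;R0,2,FALSE
HV and HV0a,HV;HV0a,2,FALSE
"H, H1, H2, H3 and H4",H;H1;H2;H3;H4,71,TRUE
H,H,25,TRUE
H1,H1,26,TRUE
H2,H2,4,FALSE
H3,H3,8,FALSE
H4,H4,8,TRUE
V,V,3,FALSE
J1 and J2a,J1;J2a,14,TRUE
J1,J1,13,TRUE
J2a,J2a,1,FALSE
"T, T1 and T2",T;T1;T2,21,TRUE
T,T,1,FALSE
T1,T1,4,FALSE
T2,T2,16,TRUE
U and U5,U;U5,18,TRUE
U,U,7,FALSE
U5,U5,11,TRUE
K,K,11,TRUE
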