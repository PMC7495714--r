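row_label,members,n_control,pct_control,n_psp,pct_psp,n_cbd,pct_cbd,tested_psp,tested_cbd
N,N,2,0.2,0,0.0,0,0.0,FALSE,FALSE
N1,N1,5,0.5,6,0.6,0,0.0,TRUE,FALSE
I,I,31,3.4,23,2.2,2,1.2,TRUE,TRUE
W,W,15,1.6,22,2.1,3,1.8,TRUE,TRUE
X,X,8,0.9,18,1.7,5,2.9,TRUE,TRUE
R and R0,R;R0,6,0.7,10,1.0,2,1.2,TRUE,FALSE
HV and HV0a,HV;HV0a,22,2.4,16,1.5,2,1.2,TRUE,TRUE
"H, H1, H2, H3, and H4",H;H1;H2;H3;H4,423,46.5,469,45.0,84,49.1,TRUE,TRUE
H,H,199,21.9,200,19.2,30,17.5,TRUE,TRUE
H1,H1,145,15.9,171,16.4,31,18.1,TRUE,TRUE
H2,H2,36,4.0,34,3.3,5,2.9,TRUE,TRUE
H3,H3,32,3.5,49,4.7,9,5.3,TRUE,TRUE
H4,H4,11,1.2,15,1.4,9,5.3,TRUE,TRUE
V,V,18,2.0,29,2.8,3,1.8,TRUE,TRUE
JT,JT,2,0.2,3,0.3,0,0.0,FALSE,FALSE
"J1, J1d, J2a, and J2b",J1;J1d;J2a;J2b,93,10.2,125,12.0,18,10.5,TRUE,TRUE
J1,J1,72,7.9,98,9.4,17,9.9,TRUE,TRUE
J1d,J1d,1,0.1,0,0.0,0,0.0,FALSE,FALSE
J2a,J2a,13,1.4,24,2.3,1,0.6,TRUE,TRUE
J2b,J2b,7,0.8,3,0.3,0,0.0,TRUE,FALSE
"T, T1, and T2",T;T1;T2,77,8.5,102,9.8,22,12.9,TRUE,TRUE
T,T,0,0.0,2,0.2,1,0.6,FALSE,FALSE
T1,T1,17,1.9,22,2.1,4,2.3,TRUE,TRUE
T2,T2,60,6.6,78,7.5,17,9.9,TRUE,TRUE
"U, U1, U3, U5, and U6",U;U1;U3;U5;U6,130,14.3,138,13.2,19,11.1,TRUE,TRUE
U,U,44,4.8,56,5.4,7,4.1,TRUE,TRUE
U1,U1,1,0.1,1,0.1,0,0.0,FALSE,FALSE
U3,U3,8,0.9,0,0.0,0,0.0,FALSE,FALSE
U5,U5,74,8.1,80,7.7,12,7.0,TRUE,TRUE
U6,U6,3,0.3,1,0.1,0,0.0,FALSE,FALSE
K,K,78,8.6,80,7.7,11,6.4,TRUE,TRUE
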