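group,variable,level,numerator,denominator,printed_pct
PSP,sex,Male,564,1042,54.1
PSP,sex,Female,478,1042,45.9
CBD,sex,Male,89,171,52.0
CBD,sex,Female,82,171,48.0
control,sex,Male,388,910,42.6
control,sex,Female,522,910,57.4
PSP,clinical_subtype,Richardson,568,763,74.4
PSP,clinical_subtype,Non-Richardson,195,763,25.6
PSP,braak,0,113,764,14.8
PSP,braak,I,127,764,16.6
PSP,braak,II,223,764,29.2
PSP,braak,III,234,764,30.6
PSP,braak,IV,50,764,6.5
PSP,braak,V,11,764,1.4
PSP,braak,VI,6,764,0.8
CBD,braak,0,20,150,13.3
CBD,braak,I,32,150,21.3
CBD,braak,II,50,150,33.3
CBD,braak,III,39,150,26.0
CBD,braak,IV,7,150,4.7
CBD,braak,V,1,150,0.7
CBD,braak,VI,1,150,0.7
PSP,thal,0,336,764,44.0
PSP,thal,1,125,764,16.4
PSP,thal,2,52,764,6.8
PSP,thal,3,188,764,24.6
PSP,thal,4,43,764,5.6
PSP,thal,5,20,764,2.6
CBD,thal,0,82,150,54.7
CBD,thal,1,30,150,20.0
CBD,thal,2,14,150,9.3
CBD,thal,3,19,150,12.7
CBD,thal,4,3,150,2.0
CBD,thal,5,2,150,1.3
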