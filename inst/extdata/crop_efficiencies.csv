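plant_type,crop_type,crop,ei,ec,ep
C4,perennial grass,Sugarcane,95.0,8.0,81.2
C4,grain,Maize,55.0,8.7,47.1
C4,grain,Sorghum,50.1,8.0,20.0
C3,grain,Winter wheat,97.8,7.5,44.0
C3,grain,Rice,80.0,6.6,62.0
C3,leguminous,Soybean,89.0,4.3,60.0
C3,tuber root,Sugar beet,90.0,6.2,86.0
C3,tuber root,Cassava,64.0,1.4,70.5
C3,tuber root,Sweetpotato,91.0,3.4,46.0
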