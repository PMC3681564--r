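"roi_id","label","role","h_min_ppm","h_max_ppm","c_min_ppm","c_max_ppm","color"
"S26","S2/6","S","6.4500","6.9500","102.0000","106.0000",
"Sp26","S'2/6","S'","7.1500","7.5000","105.0000","108.0000",
"G2","G2","G","6.7500","7.2000","108.8000","113.2000",
"Gp2","G'2","G'","7.3000","7.6500","110.4000","114.6000",
"H26","H2/6","H","7.0500","7.4200","126.0000","130.0000",
"G56","G5/6","other","6.6000","7.0200","114.2000","119.8000",
"LBa","LBa","other","6.9000","7.3000","120.6000","124.4000",
"R55","","unassigned","6.0500","6.4500","108.0000","112.0000",
"R66","","unassigned","7.5500","7.9500","124.0000","128.0000",
"OVA","","unassigned","7.5000","7.8600","130.2000","133.2000",
"OVB","","unassigned","7.7000","8.0600","131.4000","134.4000",
"X01","","other","6.0500","6.5000","130.0000","134.0000",
"X02","","other","7.6000","8.0000","100.0000","104.5000",
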