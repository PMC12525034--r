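wavelength_nm,eps_water_mm1,eps_lipid_mm1,source
970,0.0480,0.0040,"water: approximate digitization of Kou/Segelstein pure-water absorption; lipid: approximate digitization of van Veen 2005 soybean-oil series"
1050,0.0150,0.0060,"water: approximate digitization of Kou/Segelstein pure-water absorption; lipid: approximate digitization of van Veen 2005 soybean-oil series"
1200,0.1100,0.0500,"water: approximate digitization of Kou/Segelstein pure-water absorption; lipid: approximate digitization of van Veen 2005 soybean-oil series"
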