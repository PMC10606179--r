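temperature_C,compound,concentration_mg_per_100g,sd
50,lycopene,95.56,3.92
55,lycopene,88.94,2.30
60,lycopene,73.39,2.57
65,lycopene,60.87,1.99
70,lycopene,40.42,0.84
75,lycopene,31.16,1.11
50,beta_carotene,96.22,1.56
55,beta_carotene,90.70,0.86
60,beta_carotene,80.89,2.39
65,beta_carotene,71.59,1.39
70,beta_carotene,54.32,1.01
75,beta_carotene,47.33,1.54
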