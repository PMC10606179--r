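temperature_C,slope_per_s,d_eff_m2_per_s
50,-9.5680e-5,1.0074e-9
55,-1.0493e-4,1.0226e-9
60,-1.1475e-4,1.1642e-9
65,-1.2517e-4,1.2441e-9
70,-1.3618e-4,1.3712e-9
75,-1.4780e-4,1.5350e-9
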