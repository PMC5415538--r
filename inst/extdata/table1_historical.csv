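region,metric,n_specimens,mean_mm,sd_mm
west,wing,32,96.66,2.48
west,culmen,21,18.27,1.02
central,wing,47,97.40,3.03
central,culmen,47,18.86,1.18
east,wing,60,99.34,2.92
east,culmen,60,20.65,1.25
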