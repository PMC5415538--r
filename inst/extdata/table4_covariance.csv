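location,period,n_pairs,covariance_mm2,slope
james_bay,1975-1982,25168,1.661,0.257
east,1980-1987,388,1.609,0.299
fundy,1981-1989,5998,1.725,0.207
central,"1991-1992, 1994",22,1.907,0.325
west,1993-1996,555,1.085,0.143
east,2004-2005,50,2.747,0.336
west,2011-2012,159,0.885,0.111
east,2013,34,1.177,0.109
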