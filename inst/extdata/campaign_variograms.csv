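day,variable,model,nugget,sill,ratio,range_m,r2
Day1,flux,gaussian,0.035,0.436,0.080,18.05,0.706
Day1,flux_x_temp,spherical,0.181,0.434,0.417,29.88,1.761
Day2,flux,gaussian,0.031,0.442,0.070,32.11,0.915
Day2,flux_x_temp,spherical,0.232,0.542,0.428,30.59,0.887
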