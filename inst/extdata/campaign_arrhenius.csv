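day,CR,a,b,S_TP,S_TT,T_bar,t_crit
Day1,0.6058,0.0037,0.3497,0.65,6.38,25.89,1.761
Day2,0.5701,0.1331,0.1370,0.74,8.28,27.18,1.761
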