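shark,model,k,k_warm,k_cool,ratio,tm_dot,mae,aic
Mako 1,constant,0.0071,NA,NA,1.0,0.029,0.566,-901.4
Mako 1,variable,NA,0.052,0.0036,14.4,0.0062,0.243,-3119.1
Mako 2,constant,0.0015,NA,NA,1.0,0.0068,0.652,-388.6
Mako 2,variable,NA,0.075,0.0016,46.9,0.0017,0.405,-1366.3
Mako 3,constant,0.019,NA,NA,1.0,0.030,0.291,-2969.6
Mako 3,variable,NA,0.032,0.015,2.1,0.016,0.216,-3729.9
Mako 4,constant,0.0058,NA,NA,1.0,0.012,0.164,-2212.0
Mako 4,variable,NA,0.0021,0.0072,0.29,0.015,0.157,-2306.4
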