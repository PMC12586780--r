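response,group,coefficient,exponent
k_warm,endothermic,0.11,-0.21
k_cool,endothermic,0.11,-0.68
ratio,endothermic,0.70,0.61
k_warm,ectothermic,0.16,-0.50
k_cool,ectothermic,0.11,-0.54
ratio,ectothermic,1.4,0.064
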