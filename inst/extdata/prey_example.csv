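name,e_mg,k_mg,s_mg,h_s,a_cm2_s,density_per_m2
loripes,3,20,3,1,4,600
dosinia,5,85,0,1,4,80
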