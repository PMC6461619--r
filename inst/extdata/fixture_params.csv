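name,reference,class,lower,upper
vmax_amtb,150,II,1.5,15000
km_amtb,0.01,I,0.001,0.1
p_diff,50,II,0.5,5000
vmax_gs,5,II,0.05,500
km_gs,0.02,I,0.002,0.2
k_glnk,0.02,II,0.0002,2
n_glnk,2,US,2,2
mu_max,4,I,0.4,40
k_growth,1,III,0.001,1000
k_dil,0.05,US,0.05,0.05
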