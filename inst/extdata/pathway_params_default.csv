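name,value
ac_base,0
k_camp_f,49.5
k_camp_i,2.47
v0,101
pde3_rel,1
K_pde3,1
k_pka_f,60.5
k_pka_r,10
k_gp_f,25
alpha,1.2
k_gp_r,3.36
k_cftr_f,181
beta,6.3
k_cftr_r,11.3
k_atp_flux,2
gp_total,1
pka_total,1
cftr_total,1
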