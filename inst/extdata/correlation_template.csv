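name,mu_u,g_u,m_u,delta_Vmax,Vu10,W0,Rb,IVu50,k1,k2,IC50
mu_u,1,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA
g_u,NA,1,NA,NA,NA,NA,NA,NA,NA,NA,NA
m_u,NA,NA,1,NA,NA,NA,NA,NA,NA,NA,NA
delta_Vmax,NA,NA,NA,1,NA,NA,NA,NA,NA,NA,NA
Vu10,NA,NA,NA,NA,1,NA,NA,NA,NA,NA,NA
W0,NA,NA,NA,NA,NA,1,NA,NA,NA,NA,NA
Rb,NA,NA,NA,NA,NA,NA,1,NA,NA,NA,NA
IVu50,NA,NA,NA,NA,NA,NA,NA,1,NA,NA,NA
k1,NA,NA,NA,NA,NA,NA,NA,NA,1,NA,NA
k2,NA,NA,NA,NA,NA,NA,NA,NA,NA,1,0.95
IC50,NA,NA,NA,NA,NA,NA,NA,NA,NA,0.95,1
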