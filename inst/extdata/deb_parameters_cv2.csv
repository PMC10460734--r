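name,value,cv_percent,family,units
mu_u,13.321,50,lognormal,-
g_u,10.607,50,lognormal,-
m_u,1.459e-2,80,lognormal,1/day
delta_Vmax,4.146e-2,60,lognormal,cm3/day
Vu10,1.160e-3,60,lognormal,g
W0,22.263,5,lognormal,g
Rb,7.310e-2,80,lognormal,-
IVu50,5.300,60,lognormal,cm3
k1,0.381,80,lognormal,1/day
k2,0.129,40,lognormal,ml/(ng day)
IC50,2.530e-2,60,lognormal,ng/ml
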