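enzyme,kcat_km_asp,kcat_km_aromatic,reported_ratio,cohort
eAAT,90800,119,760,previous
eTAT,37000,960000,0.038,previous
AtmAT,36000,8.8,4100,new
CecAT,34000,0.45,80000,new
CtAT,37000,80,470,new
GicAT,10200,47000,0.22,new
PfcAT,35000,3.0,12000,new
PaAT,47000,47,1000,new
SccAT,63000,18,3600,new
ScmAT,14000,3.1,5000,new
TbcAT,11000,22000,0.49,new
TbmAT,132,22.0,6.0,new
VcAT,680,67000,0.010,new
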