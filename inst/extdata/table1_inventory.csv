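variable,unit,PP,WC,HS
area,ha,21.61,20.85,21.45
fertiliser_area,ha,21.24,20.52,21.03
fym_area,ha,18.90,17.97,18.34
yield,kg DM/ha,11474,10780,10417
fertiliser_n,kg,4951,681,4346
fertiliser_p,kg,206,1125,208
fertiliser_k,kg,554,454,312
lime,kg,0,3002,4361
fym,t,118,118,98
glyphosate,kg,0,7.51,15.25
fluroxypyr,kg,0,0,0.98
seed_grass,kg,0,734,650
seed_clover,kg,0,42,0
diesel,l,342,1181,1295
soybean,kg,651,651,672
straw,kg,38920,39894,39685
tkm_soybean_sea,tkm,6267,6267,6469
tkm_soybean_road,tkm,155,155,160
tkm_straw_road,tkm,2436,2497,2484
tkm_fertiliser_road,tkm,2444,2252,3949
pasture_de,%,77.55,77.7,76.78
pasture_cp,%,20.72,20.12,17.41
silage_de,%,65.76,64.05,64.66
silage_cp,%,11.44,9.24,11.92
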