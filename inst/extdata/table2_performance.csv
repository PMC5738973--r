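parameter,unit,pp_mean,pp_sd,wc_mean,wc_sd,hs_mean,hs_sd,p_value
entry_weight,kg,279,32.08,279,28.76,284,35.76,0.80
finishing_weight,kg,607,50.75,582,47.15,590,39.23,0.12
total_growth,kg,328,41.68,304,45.73,307,38.67,0.05
days_on_platform,d,448,40.33,461,43.68,453,31.97,0.46
adg,kg/d,0.76,0.10,0.68,0.10,0.70,0.08,<0.01
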