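item,FW,WS,FW_sd,WS_sd
dry_matter_pct,80.67,85.48,14.00,12.00
ash_pct,6.67,8.60,0.29,1.10
crude_fat_pct,1.27,1.62,0.47,0.29
adf_pct,40.60,37.89,0.86,2.72
ndf_pct,60.83,56.54,2.08,3.33
nfc_pct,16.32,21.17,3.54,3.69
starch_pct,3.75,7.08,0.94,3.21
crude_protein_pct,11.35,10.80,1.79,1.83
tdn_pct_dm,57.27,59.38,0.67,2.12
neg_mcal_kg,0.65,0.72,0.02,0.06
nem_mcal_kg,1.37,1.44,0.02,0.06
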