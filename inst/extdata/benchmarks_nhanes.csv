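metric,summary_key,comparison,reference_value,ref_low,ref_high,source
energy_kcal_per_day,energy_mean,signed_deviation,2100.0,1600,2500,NHANES 2017-2018 mean intake
protein_g_per_day,protein_mean,signed_deviation,82.0,65,100,NHANES 2017-2018 mean intake
calcium_mg_per_day,calcium_mean,signed_deviation,950.0,650,1200,NHANES 2017-2018 mean intake
iron_mg_per_day,iron_mean,signed_deviation,15.5,11,19,NHANES 2017-2018 mean intake
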