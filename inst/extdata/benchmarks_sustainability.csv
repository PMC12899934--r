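metric,summary_key,comparison,reference_value,ref_low,ref_high,source
ghg_kgco2e_per_day,ghg_mean,lt,5.0,,,EAT-Lancet planetary health diet threshold
water_l_per_day,water_mean,lt,5000,,,Water footprint literature
iron_adequacy_pct,iron_adequacy_pct,gt,90,,,DRI population adequacy target
calcium_adequacy_pct,calcium_adequacy_pct,gt,90,,,DRI population adequacy target
mediterranean_minus_western_ghg,med_minus_west_ghg,lt,0,,,Dietary sustainability meta-analyses
dietary_diversity_score,diversity_mean,range,,8,15,FAO dietary diversity guidance
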