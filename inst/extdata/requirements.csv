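nutrient,sex,threshold,kind
iron_mg,male,8,EAR
iron_mg,female,18,EAR
calcium_mg,male,1000,EAR
calcium_mg,female,1000,EAR
zinc_mg,male,11,EAR
zinc_mg,female,8,EAR
vitd_ug,male,20,RDA
vitd_ug,female,20,RDA
b12_ug,male,6,RDA
b12_ug,female,6,RDA
protein_g_per_kg,male,0.8,RDA
protein_g_per_kg,female,0.8,RDA
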