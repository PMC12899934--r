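group,energy_kcal,energy_sd,protein_g,protein_sd,iron_mg,iron_sd,calcium_mg,calcium_sd,ghg_kgco2e,ghg_sd,water_l,water_sd,price_usd,price_sd,n_foods
Animal,189.4,68.8,24.2,5.6,1.06,0.89,13.6,3.4,10.58,9.22,6678,4964,11.50,3.87,5
Dairy,275.0,285.9,10.5,9.5,0.54,0.76,204.8,291.0,6.90,5.52,3293,2280,6.14,5.62,5
Fruit,62.8,16.8,0.7,0.3,0.24,0.13,15.4,14.4,0.92,0.67,633,179,3.46,1.43,5
Grain,248.8,122.8,9.0,5.3,2.72,1.56,54.7,64.6,2.07,0.69,2496,1394,3.52,1.60,10
Legume,197.0,140.3,14.4,12.4,5.54,5.68,83.8,108.7,1.24,0.44,4460,1427,4.08,0.82,5
Nuts,574.0,59.8,20.0,4.2,4.84,1.84,233.6,235.5,2.08,0.58,5371,3488,17.10,6.84,5
Oil,701.4,310.6,0.4,0.9,0.30,0.28,6.6,9.0,3.44,1.61,6348,4969,8.60,4.63,5
Vegetable,39.0,24.1,1.6,0.8,0.73,0.73,33.7,26.6,1.03,0.65,276,74,2.78,0.96,10
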