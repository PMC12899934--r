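pattern,share_animal,share_dairy,share_fruit,share_grain,share_legume,share_nuts,share_oil,share_vegetable,concentration,mass_mu,mass_sigma,mass_lower,mass_upper,age_mean,age_sd,bmi_mean,bmi_sd,female_frac,income_mean,income_sd,tertiary_frac,diversity_mean,diversity_sd
Mediterranean,0.07610570085,0.00367957384362,0.3325835143,0.03980534977,0.04590238540,0.10885800188,0.05581131137,0.3372541626,12,1.891033022,0.3947118827,0.5,6,42.5,12.3,24.8,3.6,0.524,3.2,1.4,0.453,11.11,2.05
Western,0.07359476832,0.00001545583417,0.3843006216,0.03571145867,0.04807984782,0.09082323984,0.06729593525,0.3001786726,12,2.007946936,0.4849942056,0.5,6,38.7,14.2,27.3,4.8,0.489,2.8,1.3,0.327,11.20,2.01
Plant-based,0.06128319913,0.01720002634094,0.3513598549,0.04697913884,0.05504144344,0.08373815487,0.06597683988,0.3184213426,12,1.998899016,0.3339392444,0.5,6,45.8,11.6,23.1,3.2,0.562,3.5,1.3,0.584,11.04,2.01
Mixed,0.08595835799,0.00943210563820,0.3312459465,0.04770215511,0.02831702467,0.11813238926,0.06649099026,0.3127210306,12,1.854700254,0.3949126013,0.5,6,40.2,13.5,25.6,4.1,0.507,3.1,1.4,0.422,11.07,1.97
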