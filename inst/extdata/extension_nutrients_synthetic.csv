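group,zinc_mg,zinc_sd,vitd_ug,vitd_sd,b12_ug,b12_sd
Animal,0.857,0.6856,0.2403,0.1922,0.1785,0.1428
Dairy,0.8578,0.6863,0.2404,0.1923,0.1796,0.1437
Fruit,0.8539,0.6831,0.2407,0.1925,0.1784,0.1428
Grain,0.8558,0.6847,0.2403,0.1922,0.1786,0.1429
Legume,0.8529,0.6823,0.2412,0.1929,0.1784,0.1427
Nuts,0.8568,0.6854,0.24,0.192,0.1784,0.1427
Oil,0.8542,0.6833,0.2406,0.1925,0.1785,0.1428
Vegetable,0.8547,0.6838,0.2404,0.1923,0.1784,0.1427
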