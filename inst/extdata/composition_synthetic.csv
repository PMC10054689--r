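item,energy_kcal,saturated_fat_g,fat_g,sodium_mg,serv_grains,serv_vegetables,serv_fruits,serv_dairy,serv_meat,serv_nuts_seeds_legumes,serv_sweets
bread,2.5,0.005,0.03,5,0.0125,0,0,0,0,0,0
rice,1.3,0.001,0.003,0.01,0.01,0,0,0,0,0,0
vegetables_mixed,0.3,0.0005,0.002,0.3,0,0.0125,0,0,0,0,0
fruit_mixed,0.5,0.0005,0.002,0.01,0,0,0.0125,0,0,0,0
milk,0.6,0.011,0.018,0.4,0,0,0,0.004,0,0,0
cheese,3.5,0.18,0.28,6,0,0,0,0.025,0,0,0
beef,2.1,0.06,0.15,0.6,0,0,0,0,0.01,0,0
fish,1.4,0.005,0.06,0.8,0,0,0,0,0.01,0,0
nuts,6.0,0.05,0.5,0.05,0,0,0,0,0,0.035,0
legumes,1.1,0.001,0.006,0.05,0,0,0,0,0,0.007,0
chocolate,5.4,0.19,0.31,0.2,0,0,0,0,0,0,0.02
soft_drink,0.4,0,0,0.1,0,0,0,0,0,0,0.003
olive_oil,8.8,0.14,1.0,0.02,0,0,0,0,0,0,0
butter,7.2,0.51,0.81,0.11,0,0,0,0,0,0,0
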