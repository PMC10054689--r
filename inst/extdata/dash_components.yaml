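# DASH adherence score: 10 components, each scored 1 (target met),
# 0.5 (intermediate met) or 0. Thresholds follow the DASH trial targets at a
# ~2000 kcal reference diet with intermediate = roughly half-compliance;
# they are configuration, not code, and are provisional defaults meant to be
# replaced by the thresholds of the instrument actually in use.
components:
  - {name: grains,    variable: serv_grains,             unit: servings_per_day, direction: ge, target: 7.0,  intermediate: 3.5}
  - {name: vegetables, variable: serv_vegetables,        unit: servings_per_day, direction: ge, target: 4.0,  intermediate: 2.0}
  - {name: fruits,    variable: serv_fruits,             unit: servings_per_day, direction: ge, target: 4.0,  intermediate: 2.0}
  - {name: dairy,     variable: serv_dairy,              unit: servings_per_day, direction: ge, target: 2.0,  intermediate: 1.0}
  - {name: meat,      variable: serv_meat,               unit: servings_per_day, direction: le, target: 2.0,  intermediate: 3.0}
  - {name: nuts_seeds_legumes, variable: serv_nuts_seeds_legumes, unit: servings_per_day, direction: ge, target: 0.6, intermediate: 0.3}
  - {name: sweets,    variable: serv_sweets,             unit: servings_per_day, direction: le, target: 0.7,  intermediate: 1.4}
  - {name: saturated_fat, variable: saturated_fat_g,     unit: percent_energy_fat, direction: le, target: 6.0, intermediate: 11.0}
  - {name: total_fat, variable: fat_g,                   unit: percent_energy_fat, direction: le, target: 27.0, intermediate: 32.0}
  - {name: sodium,    variable: sodium_mg,               unit: mg_per_day, direction: le, target: 2300, intermediate: 3450}
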