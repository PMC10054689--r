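# The 14 binary MEDAS items (twelve food-intake questions, two food-habit
# questions). Labels document the adherence condition each 0/1 item encodes;
# the scorer itself consumes pre-coded 0/1 responses, so the exact cutoffs of
# the deployed screener live with the instrument, not with the code.
items:
  - {id: olive_oil_principal,   habit: true,  label: "olive oil as principal culinary fat"}
  - {id: olive_oil_amount,      habit: false, label: ">= 4 tablespoons olive oil per day"}
  - {id: vegetables,            habit: false, label: ">= 2 servings of vegetables per day"}
  - {id: fruit,                 habit: false, label: ">= 3 servings of fruit per day"}
  - {id: red_meat,              habit: false, label: "< 1 serving of red/processed meat per day"}
  - {id: butter_margarine,      habit: false, label: "< 1 serving of butter/margarine/cream per day"}
  - {id: sugary_drinks,         habit: false, label: "< 1 sugar-sweetened beverage per day"}
  - {id: wine,                  habit: false, label: ">= 7 glasses of wine per week"}
  - {id: legumes,               habit: false, label: ">= 3 servings of legumes per week"}
  - {id: fish_seafood,          habit: false, label: ">= 3 servings of fish/seafood per week"}
  - {id: commercial_sweets,     habit: false, label: "< 3 commercial sweets/pastries per week"}
  - {id: nuts,                  habit: false, label: ">= 3 servings of nuts per week"}
  - {id: white_over_red_meat,   habit: true,  label: "preference of white over red meat"}
  - {id: sofrito,               habit: false, label: ">= 2 servings of sofrito-style sauce per week"}
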