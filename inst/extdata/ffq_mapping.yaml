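# Crosswalk from reference-FFQ food-group intakes to MED4CHILD item
# indicators, version 1.0. A documented reconstruction from the item
# criteria; edit grams_per_serving or food_group to match another FFQ.
#
# mode:
#   grams        : servings = g/day / grams_per_serving, threshold applied
#                  on the item's period (day or week)
#   freq_grams   : use freq_<food_group> (occasions/week) when present,
#                  otherwise fall back to gram-based servings
#   preference   : white-meat vs red-meat comparison (freq preferred,
#                  grams fallback); point iff white > red
#   binary_grams : use binary column when present, otherwise point iff
#                  olive-oil grams exceed butter/cream grams
#   none         : item not derivable from the FFQ (sofrito)
#
# Serving-size ranges are collapsed to midpoints; olive oil tablespoon
# 10 mL x 0.92 g/mL = 9.2 g; beverage glass 200 mL = 200 g.
version: "1.0"
glass_g: 200
olive_oil_density_g_ml: 0.92
items:
  - item_id: 1
    mode: binary_grams
    binary_column: olive_oil_main_fat
    food_group: olive_oil
    versus_group: butter_cream
  - item_id: 2
    mode: grams
    food_group: olive_oil
    grams_per_serving: 9.2
  - item_id: 3
    mode: grams
    food_group: vegetables
    grams_per_serving: 65
  - item_id: 4
    mode: grams
    food_group: fruits
    grams_per_serving: 100
  - item_id: 5
    mode: freq_grams
    food_group: whole_grains
    grams_per_serving: 50
  - item_id: 6
    mode: grams
    food_group: fermented_dairy
    grams_per_serving: 125
  - item_id: 7
    mode: grams
    food_group: legumes
    grams_per_serving: 40
  - item_id: 8
    mode: grams
    food_group: fish_seafood
    grams_per_serving: 55
  - item_id: 9
    mode: grams
    food_group: nuts
    grams_per_serving: 17.5
  - item_id: 10
    mode: preference
    food_group: white_meat
    versus_group: red_processed_meat
    grams_per_serving: 60
  - item_id: 11
    mode: none
  - item_id: 12
    mode: freq_grams
    food_group: red_processed_meat
    grams_per_serving: 50
  - item_id: 13
    mode: grams
    food_group: butter_cream
    grams_per_serving: 12
  - item_id: 14
    mode: grams
    food_group: sugared_beverages
    grams_per_serving: 200
  - item_id: 15
    mode: freq_grams
    food_group: sweets_snacks
    grams_per_serving: 30
  - item_id: 16
    mode: freq_grams
    food_group: dairy_desserts
    grams_per_serving: 100
  - item_id: 17
    mode: freq_grams
    food_group: pastries
    grams_per_serving: 50
  - item_id: 18
    mode: freq_grams
    food_group: precooked
    grams_per_serving: 150
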