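# MED4CHILD item registry, version 1.0
# One entry per item. Units:
#   servings_per_day / servings_per_week : counts of defined servings
#   times_per_week                       : eating occasions, no serving size
#   tablespoons_per_day                  : 1 tbsp = 10 mL olive oil
#   binary_preference                    : yes/no answer (1/0)
# direction "at_least": point iff answer >= threshold
# direction "less_than": point iff answer <  threshold
# direction "yes": point iff answer == 1
# serving_g: [low, high] grams per serving where the instrument defines one.
version: "1.0"
items:
  - item_id: 1
    label: "Extra-virgin olive oil as main culinary fat"
    unit: binary_preference
    direction: "yes"
    threshold: 1
  - item_id: 2
    label: "Olive oil, 3 or more tablespoons per day"
    unit: tablespoons_per_day
    direction: at_least
    threshold: 3
    tbsp_ml: 10
  - item_id: 3
    label: "Vegetables, 2 or more servings per day"
    unit: servings_per_day
    direction: at_least
    threshold: 2
    serving_g: [50, 80]
    extra_condition: raw_or_salad_weekly
  - item_id: 4
    label: "Fruit, 3 or more small fruits per day"
    unit: servings_per_day
    direction: at_least
    threshold: 3
    serving_g: [100, 100]
  - item_id: 5
    label: "Whole grains instead of refined, 3 or more times per week"
    unit: times_per_week
    direction: at_least
    threshold: 3
  - item_id: 6
    label: "Fermented milk, plain yogurt or goat/sheep cheese, 1 or more servings per day"
    unit: servings_per_day
    direction: at_least
    threshold: 1
    serving_g: [125, 125]
  - item_id: 7
    label: "Legumes, 2-3 or more servings per week"
    unit: servings_per_week
    direction: at_least
    threshold: 2
    serving_g: [40, 40]
  - item_id: 8
    label: "Fish or seafood, 3 or more servings per week"
    unit: servings_per_week
    direction: at_least
    threshold: 3
    serving_g: [40, 70]
  - item_id: 9
    label: "Nuts, 3 or more servings per week"
    unit: servings_per_week
    direction: at_least
    threshold: 3
    serving_g: [15, 20]
  - item_id: 10
    label: "Prefers chicken, turkey or rabbit over red meat and sausages"
    unit: binary_preference
    direction: "yes"
    threshold: 1
  - item_id: 11
    label: "Sofrito, 2 or more servings per week"
    unit: servings_per_week
    direction: at_least
    threshold: 2
  - item_id: 12
    label: "Red meat, hamburgers, sausages or processed meat, less than 2 times per week"
    unit: times_per_week
    direction: less_than
    threshold: 2
  - item_id: 13
    label: "Butter or cream, less than 1 serving per day"
    unit: servings_per_day
    direction: less_than
    threshold: 1
    serving_g: [12, 12]
  - item_id: 14
    label: "Carbonated and/or sugary beverages, less than 2 glasses per week"
    unit: times_per_week
    direction: less_than
    threshold: 2
  - item_id: 15
    label: "Chips, gummies or sweets, less than 1 time per week"
    unit: times_per_week
    direction: less_than
    threshold: 1
  - item_id: 16
    label: "Dairy desserts (custard, ice cream, smoothies, petit suisse), less than 1 time per week"
    unit: times_per_week
    direction: less_than
    threshold: 1
  - item_id: 17
    label: "Pastries, stuffed cookies, sweets or cakes, less than 2 times per week"
    unit: times_per_week
    direction: less_than
    threshold: 2
  - item_id: 18
    label: "Pre-cooked or ready-to-eat food, less than 1 time per week"
    unit: times_per_week
    direction: less_than
    threshold: 1
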