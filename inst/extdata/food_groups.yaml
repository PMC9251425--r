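# Default 17-group classification for PDI/hPDI scoring.
# category: healthy_plant | unhealthy_plant | animal
# item_codes: optional food-composition item-code -> group_id lookup
# (a small illustrative subset; extend with the coding scheme in use).
groups:
  - {group_id: whole_grains, name: Whole grains, category: healthy_plant}
  - {group_id: fruits, name: Fruits, category: healthy_plant}
  - {group_id: vegetables, name: Vegetables, category: healthy_plant}
  - {group_id: nuts, name: Nuts, category: healthy_plant}
  - {group_id: legumes, name: Legumes, category: healthy_plant}
  - {group_id: tea_coffee, name: Tea and coffee, category: healthy_plant}
  - {group_id: vegetable_oils, name: Vegetable oils, category: healthy_plant}
  - {group_id: refined_grains, name: Refined grains, category: unhealthy_plant}
  - {group_id: potatoes, name: Potatoes, category: unhealthy_plant}
  - {group_id: sugary_drinks, name: Sugary drinks, category: unhealthy_plant}
  - {group_id: sweets_desserts, name: Sweets and desserts, category: unhealthy_plant}
  - {group_id: fermented_preserved, name: Preserved and fermented foods, category: unhealthy_plant}
  - {group_id: animal_fats, name: Animal fats, category: animal}
  - {group_id: dairy, name: Dairy products, category: animal}
  - {group_id: eggs, name: Eggs, category: animal}
  - {group_id: fish_seafood, name: Fish or seafood, category: animal}
  - {group_id: meat, name: Meat, category: animal}
item_codes:
  "011101": refined_grains
  "012001": whole_grains
  "031101": legumes
  "041201": vegetables
  "061101": fruits
  "081101": meat
  "121101": eggs
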