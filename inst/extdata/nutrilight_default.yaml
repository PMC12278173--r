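# NutriLight default scoring configuration.
#
# Recommended daily amounts (g/day) follow the EAT-Lancet Commission reference
# diet at a 2500 kcal/day reference energy intake (Willett et al. 2019, Lancet
# 393:447-492), taking range midpoints where the Commission prints a range:
# grains 232 (all whole), vegetables 300, fruits 200, dry legumes 50 + soy 25,
# peanuts 25 + tree nuts 25, poultry 29, dairy 250, eggs 13, fish 28,
# unsaturated plant oils 40, starchy vegetables/tubers 50, red meat 14,
# animal fats (lard/tallow) 5, added sugars 31. The reference diet sets no
# separate refined-grain amount (its grain target is entirely whole grain);
# the 100 g/day moderation allowance used here is a NutriLight adaptation.
# Every value is a regional-adaptation point: edit freely and reload.
reference_energy_kcal: 2500
yellow_tolerance: 0
groups:
  - name: whole_grains
    category: green
    recommended_intake_g: 232
    display_label: Whole grains
  - name: vegetables
    category: green
    recommended_intake_g: 300
    display_label: Vegetables
  - name: fruits
    category: green
    recommended_intake_g: 200
    display_label: Fruits
  - name: soy_legumes
    category: green
    recommended_intake_g: 75
    display_label: Soy and legumes
  - name: nuts
    category: green
    recommended_intake_g: 50
    display_label: Nuts
  - name: refined_grains
    category: yellow
    recommended_intake_g: 100
    display_label: Refined grains
  - name: poultry
    category: yellow
    recommended_intake_g: 29
    display_label: Poultry
  - name: dairy
    category: yellow
    recommended_intake_g: 250
    display_label: Dairy foods
  - name: eggs
    category: yellow
    recommended_intake_g: 13
    display_label: Eggs
  - name: fish_seafood
    category: yellow
    recommended_intake_g: 28
    display_label: Fish and seafood
  - name: plant_oils
    category: yellow
    recommended_intake_g: 40
    display_label: Plant oils
  - name: starchy_vegetables
    category: yellow
    recommended_intake_g: 50
    display_label: Starchy vegetables
  - name: red_meat
    category: red
    recommended_intake_g: 14
    display_label: Red meat
  - name: animal_oils
    category: red
    recommended_intake_g: 5
    display_label: Animal oils
  - name: added_sugars
    category: red
    recommended_intake_g: 31
    display_label: Added sugars
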