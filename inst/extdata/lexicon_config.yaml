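# Example lexicon configuration. Every key is optional; omitted keys fall
# back to the built-in defaults (see ?build_lexicon).
seeds:
  - hashish
medical_terms: []
default_threshold: 0.70
thresholds:
  hashish: 0.80
misspellings:
  marijuana:
    - marihuana
exclusions:
  bile_duct:
    - abdominal
    - gallbladder
    - pancreas
    - common bile duct
    - biliary
  allergy:
    - pollen
    - allergy
    - allergies
    - allergic
    - allergen
    - allergens
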