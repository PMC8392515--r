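latents:
  ses:
  - age_father
  - age_mother
  - edu_father
  - edu_mother
  - income_mother
  - income_father
  lifestyle:
  - sleep
  - physical_activity
  - screen_time
  - pocket_money
  healthy:
  - fruits
  - vegetables
  - whole_grains
  unhealthy:
  - snacks
  - fast_food
  - soft_drink
  - sweets
outcomes:
- bmi
- body_fat
controls:
- parent_bmi
- parent_body_fat
paths:
- source: ses
  target: healthy
  role: structural
- source: ses
  target: unhealthy
  role: structural
- source: ses
  target: lifestyle
  role: structural
- source: ses
  target: bmi
  role: structural
- source: ses
  target: body_fat
  role: structural
- source: lifestyle
  target: healthy
  role: structural
- source: lifestyle
  target: unhealthy
  role: structural
- source: lifestyle
  target: bmi
  role: structural
- source: lifestyle
  target: body_fat
  role: structural
- source: healthy
  target: bmi
  role: structural
- source: healthy
  target: body_fat
  role: structural
- source: unhealthy
  target: bmi
  role: structural
- source: unhealthy
  target: body_fat
  role: structural
- source: parent_bmi
  target: bmi
  role: control
- source: parent_body_fat
  target: body_fat
  role: control
group_variable: gender
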