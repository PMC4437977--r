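# Ramachandran risk score: age, BMI, family history (any member),
# physical activity (sedentary vs active), waist.
name: ramachandran
label: Ramachandran risk score
cut_point: 21
items:
  - factor: age
    type: numeric
    closed: left
    breaks: [30, 45, 60]
    points: [0, 10, 18, 19]
  - factor: bmi
    type: numeric
    closed: left
    breaks: [25]
    points: [0, 7]
  - factor: family_history
    type: categorical
    points:
      none: 0
      one_parent_or_sibling: 7
      both_parents: 7
  - factor: physical_activity
    type: categorical
    points:
      regular_exercise_and_strenuous_work: 0
      one_of_the_two: 0
      neither: 4
  - factor: waist
    type: numeric
    closed: left
    sex_breaks:
      female: [80]
      male: [85]
    points: [0, 5]
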