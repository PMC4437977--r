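# Mohan risk score (Indian Diabetes Risk Score): age, family history,
# physical activity, waist.
name: mohan
label: Mohan risk score (Indian Diabetes Risk Score)
cut_point: 60
items:
  - factor: age
    type: numeric
    closed: left
    breaks: [35, 50]
    points: [0, 20, 30]
  - factor: family_history
    type: categorical
    points:
      none: 0
      one_parent_or_sibling: 10
      both_parents: 20
  - factor: physical_activity
    type: categorical
    points:
      regular_exercise_and_strenuous_work: 0
      one_of_the_two: 20
      neither: 30
  - factor: waist
    type: numeric
    closed: left
    sex_breaks:
      female: [80, 90]
      male: [90, 100]
    points: [0, 10, 20]
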