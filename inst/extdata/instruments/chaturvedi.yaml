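# Chaturvedi risk score: age, blood pressure, family history, waist.
# Blood pressure scores the worse of the systolic and diastolic categories.
# Waist bands are right-closed so the categories are exhaustive over
# continuous waist circumference.
name: chaturvedi
label: Chaturvedi risk score
cut_point: 16
items:
  - factor: age
    type: numeric
    closed: left
    breaks: [40, 50]
    points: [0, 4, 6]
  - factor: blood_pressure
    type: max_of
    components:
      - factor: sbp
        type: numeric
        closed: left
        breaks: [120, 140]
        points: [0, 5, 7]
      - factor: dbp
        type: numeric
        closed: left
        breaks: [80, 90]
        points: [0, 5, 7]
  - factor: family_history
    type: categorical
    points:
      none: 0
      one_parent_or_sibling: 4
      both_parents: 4
  - factor: waist
    type: numeric
    closed: right
    sex_breaks:
      female: [75, 85]
      male: [80, 90]
    points: [0, 9, 12]
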