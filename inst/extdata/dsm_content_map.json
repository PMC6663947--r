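{
  "criteria": [
    {"criterion_id": "c01", "label": "Depressed mood most of day", "item_nos": [4, 3]},
    {"criterion_id": "c02", "label": "Little interest or pleasure in doing things", "item_nos": [18, 9]},
    {"criterion_id": "c03", "label": "Symptoms: psychomotor retardation or agitation", "item_nos": [46]},
    {"criterion_id": "c04", "label": "Symptoms: insomnia/hypersomnia", "item_nos": []},
    {"criterion_id": "c05", "label": "Symptoms: fatigue", "item_nos": [39]},
    {"criterion_id": "c06", "label": "Symptoms: worthlessness", "item_nos": [24, 2, 6]},
    {"criterion_id": "c07", "label": "Symptoms: excessive guilt", "item_nos": [37]},
    {"criterion_id": "c08", "label": "Symptoms: diminished ability to think/concentrate or indecisiveness", "item_nos": [26]},
    {"criterion_id": "c09", "label": "Symptoms: suicidal ideation", "item_nos": [13, 8]},
    {"criterion_id": "c10", "label": "Symptoms: significant weight gain or loss/appetite loss", "item_nos": [48, 50, 51]},
    {"criterion_id": "c11", "label": "Significant distress or impairment", "item_nos": [5, 11, 25]}
  ],
  "extra_symptom_rows": [
    {"label": "Symptoms: hopeless", "item_nos": [1]},
    {"label": "Symptoms: helpless", "item_nos": [7]},
    {"label": "Symptoms: withdrew from others", "item_nos": [25]}
  ],
  "short_form_1": [4, 18, 46, 39, 24, 37, 26, 13, 1, 25],
  "short_form_2": [4, 3, 9, 2, 6, 8, 5, 11, 1, 7]
}
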