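# In silico closed-loop run: 15-factor grid against a randomly drawn
# synthetic cell-response landscape (see ?random_cell_landscape).
seed: 1
engine:
  replicates: 3
  max_generations: 25
evaluator:
  type: synthetic
  sigma: 0.2
factors:
- {name: F01, unit: au, doses: [0, 1, 2, 3, 4, 5]}
- {name: F02, unit: au, doses: [0, 1, 2, 3, 4, 5]}
- {name: F03, unit: au, doses: [0, 1, 2, 3, 4, 5]}
- {name: F04, unit: au, doses: [0, 1, 2, 3, 4, 5]}
- {name: F05, unit: au, doses: [0, 1, 2, 3, 4, 5]}
- {name: F06, unit: au, doses: [0, 1, 2, 3, 4, 5]}
- {name: F07, unit: au, doses: [0, 1, 2, 3, 4, 5]}
- {name: F08, unit: au, doses: [0, 1, 2, 3, 4, 5]}
- {name: F09, unit: au, doses: [0, 1, 2, 3, 4, 5]}
- {name: F10, unit: au, doses: [0, 1, 2, 3, 4, 5]}
- {name: F11, unit: au, doses: [0, 1, 2, 3, 4, 5]}
- {name: F12, unit: au, doses: [0, 1, 2, 3, 4, 5]}
- {name: F13, unit: au, doses: [0, 1, 2, 3, 4, 5]}
- {name: F14, unit: au, doses: [0, 1, 2, 3, 4, 5]}
- {name: F15, unit: au, doses: [0, 1, 2, 3, 4, 5]}
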