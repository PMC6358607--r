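# In silico benchmark run: 15-factor, 5-level noisy Rosenbrock grid.
seed: 1
engine:
  replicates: 3
  max_generations: 25
  carried_termination: false   # trace the full performance curve
evaluator:
  type: benchmark
  noise_sd: 0.05
factors:
- {name: X01, unit: au, doses: [0, 1, 2, 3, 4]}
- {name: X02, unit: au, doses: [0, 1, 2, 3, 4]}
- {name: X03, unit: au, doses: [0, 1, 2, 3, 4]}
- {name: X04, unit: au, doses: [0, 1, 2, 3, 4]}
- {name: X05, unit: au, doses: [0, 1, 2, 3, 4]}
- {name: X06, unit: au, doses: [0, 1, 2, 3, 4]}
- {name: X07, unit: au, doses: [0, 1, 2, 3, 4]}
- {name: X08, unit: au, doses: [0, 1, 2, 3, 4]}
- {name: X09, unit: au, doses: [0, 1, 2, 3, 4]}
- {name: X10, unit: au, doses: [0, 1, 2, 3, 4]}
- {name: X11, unit: au, doses: [0, 1, 2, 3, 4]}
- {name: X12, unit: au, doses: [0, 1, 2, 3, 4]}
- {name: X13, unit: au, doses: [0, 1, 2, 3, 4]}
- {name: X14, unit: au, doses: [0, 1, 2, 3, 4]}
- {name: X15, unit: au, doses: [0, 1, 2, 3, 4]}
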