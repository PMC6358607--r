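# Example 15-factor search space for a suspension-cell expansion screen.
# Factor names follow common media-screen supplements; dose grids are
# illustrative (synthetic) concentrations, not measured reference values.
factors:
- name: GMCSF
  unit: ng/ml
  doses: [0.0, 0.1, 0.5, 2.0, 8.0, 32.0]
- name: SCF
  unit: ng/ml
  doses: [0.0, 1.0, 5.0, 20.0, 80.0]
- name: ITS
  unit: x
  doses: [0.0, 0.25, 0.5, 1.0, 2.0, 4.0]
- name: bME
  unit: uM
  doses: [0.0, 12.5, 25.0, 50.0, 100.0]
- name: ALB
  unit: mg/ml
  doses: [0.0, 1.0, 2.5, 5.0, 10.0, 20.0]
- name: LIP
  unit: x
  doses: [0.0, 0.5, 1.0, 2.0]
- name: PYR
  unit: mM
  doses: [0.0, 0.5, 1.0, 2.0, 4.0]
- name: GLN
  unit: mM
  doses: [0.0, 1.0, 2.0, 4.0, 8.0, 16.0]
- name: NEAA
  unit: x
  doses: [0.0, 0.5, 1.0, 2.0]
- name: VITS
  unit: x
  doses: [0.0, 0.5, 1.0, 2.0]
- name: SEL
  unit: nM
  doses: [0.0, 10.0, 30.0, 90.0, 270.0]
- name: TRF
  unit: ug/ml
  doses: [0.0, 2.5, 5.0, 10.0, 20.0, 40.0]
- name: SP6
  unit: uM
  doses: [0.0, 0.3, 1.0, 3.0, 10.0]
- name: CHIR
  unit: uM
  doses: [0.0, 0.3, 1.0, 3.0, 10.0]
- name: ASC
  unit: ug/ml
  doses: [0.0, 12.5, 25.0, 50.0, 100.0, 200.0]
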