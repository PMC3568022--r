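species:
- X1
- X2
- X3
- X4
initial_conditions:
  X1: 1.4
  X2: 2.7
  X3: 1.2
  X4: 0.4
fluxes:
  v1:
    gamma: 12.0
    orders:
      X3: -0.8
  v2:
    gamma: 8.0
    orders:
      X1: 0.5
  v3:
    gamma: 3.0
    orders:
      X2: 0.75
  v4:
    gamma: 5.0
    orders:
      X3: 0.5
      X4: 0.2
  v5:
    gamma: 2.0
    orders:
      X1: 0.5
  v6:
    gamma: 6.0
    orders:
      X4: 0.8
stoichiometry:
- - X1
  - v1
  - 1.0
- - X1
  - v2
  - -1.0
- - X1
  - v5
  - -1.0
- - X2
  - v2
  - 1.0
- - X2
  - v3
  - -1.0
- - X3
  - v3
  - 1.0
- - X3
  - v4
  - -1.0
- - X4
  - v5
  - 1.0
- - X4
  - v6
  - -1.0
bounds:
- flux: v1
  parameter: gamma
  lower: 0.0
  upper: 25.0
- flux: v1
  parameter: X3
  lower: -2.0
  upper: 0.0
- flux: v2
  parameter: gamma
  lower: 0.0
  upper: 25.0
- flux: v2
  parameter: X1
  lower: 0.0
  upper: 2.0
- flux: v3
  parameter: gamma
  lower: 0.0
  upper: 25.0
- flux: v3
  parameter: X2
  lower: 0.0
  upper: 2.0
- flux: v4
  parameter: gamma
  lower: 0.0
  upper: 25.0
- flux: v4
  parameter: X3
  lower: 0.0
  upper: 2.0
- flux: v4
  parameter: X4
  lower: 0.0
  upper: 2.0
- flux: v5
  parameter: gamma
  lower: 0.0
  upper: 25.0
- flux: v5
  parameter: X1
  lower: 0.0
  upper: 2.0
- flux: v6
  parameter: gamma
  lower: 0.0
  upper: 25.0
- flux: v6
  parameter: X4
  lower: 0.0
  upper: 2.0
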