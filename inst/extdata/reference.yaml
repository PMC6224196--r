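nCells: 14
cellDiameter: 10.0
sources:
- pos_um: 0.0
  strength: 10.0
contact:
  p0: 1.0
  rho_um: 40.0
  deliver_prob: 0.9
  events_per_contact: 500.0
uptake: 0.05
deltaC: 0.2
thresholds:
  sty: 5.0
  pnt: 0.92
  cut: 0.8464
  yan: 0.055
hillN:
  sty: 4.0
  pnt: 0.5
  cut: 1.0
  yan: 3.0
inhibition:
  w_KP: 0.1
  w_YP: 0.15
  w_PK: 0.05
  w_PY: 0.3
cytoneme:
  n_base: 2.0
  n_floor: 1.0
  n_cap: 12.0
  alpha: 2.5
  beta: 2.5
  gamma: 2.0
receptor:
  B_base: 0.6
  B_floor: 0.1
  B_cap: 2.0
  alpha: 1.2
  beta: 0.4
  gamma: 0.3
longFrac:
  f0: 0.05
  f1: 0.65
  p_min: 0.35
  short_share: 0.7
relax: 0.2
tol: 1.0e-08
maxSteps: 100000
mode: deterministic
finitePool: no
poolProduction: 50.0
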