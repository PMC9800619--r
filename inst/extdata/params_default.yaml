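'n':
  value: 2.0
  unit: dimensionless
  lower: 1.0
  upper: 4.0
kTD:
  value: 3.784
  unit: per day
  lower: 0.001
  upper: 100.0
lTD:
  value: 1.892
  unit: a.u.
  lower: 0.01
  upper: 10.0
dTNF:
  value: 2.0
  unit: per day
  lower: 0.001
  upper: 100.0
kI1D:
  value: 0.559
  unit: per day
  lower: 0.001
  upper: 100.0
lI1D:
  value: 1.892
  unit: a.u.
  lower: 0.01
  upper: 10.0
kI1P65:
  value: 2.162
  unit: per day
  lower: 0.001
  upper: 100.0
lI1P65:
  value: 0.7
  unit: a.u.
  lower: 0.01
  upper: 10.0
dIL1:
  value: 1.5
  unit: per day
  lower: 0.001
  upper: 100.0
kI6D:
  value: 1.135
  unit: per day
  lower: 0.001
  upper: 100.0
lI6D:
  value: 1.892
  unit: a.u.
  lower: 0.01
  upper: 10.0
kI6P65:
  value: 1.2
  unit: per day
  lower: 0.001
  upper: 100.0
lI6P65:
  value: 0.7
  unit: a.u.
  lower: 0.01
  upper: 10.0
dIL6:
  value: 1.5
  unit: per day
  lower: 0.001
  upper: 100.0
kP650:
  value: 0.1
  unit: per day
  lower: 0.001
  upper: 100.0
kP65TNF:
  value: 1.432
  unit: per day
  lower: 0.001
  upper: 100.0
lP65TNF:
  value: 0.8
  unit: a.u.
  lower: 0.01
  upper: 10.0
kP65IL17:
  value: 4.032
  unit: per day
  lower: 0.001
  upper: 100.0
lP65IL17:
  value: 1.021
  unit: a.u.
  lower: 0.01
  upper: 10.0
lP65I17R:
  value: 0.7798
  unit: a.u.
  lower: 0.01
  upper: 10.0
dP65:
  value: 2.155
  unit: per day
  lower: 0.001
  upper: 100.0
kST0:
  value: 0.08
  unit: per day
  lower: 0.001
  upper: 100.0
kSTIL6:
  value: 1.374
  unit: per day
  lower: 0.001
  upper: 100.0
lSTIL6:
  value: 0.7
  unit: a.u.
  lower: 0.01
  upper: 10.0
lSTGp:
  value: 0.5379
  unit: a.u.
  lower: 0.01
  upper: 10.0
kSTIL1:
  value: 0.1432
  unit: per day
  lower: 0.001
  upper: 100.0
lSTIL1:
  value: 0.7
  unit: a.u.
  lower: 0.01
  upper: 10.0
dST:
  value: 0.8
  unit: per day
  lower: 0.001
  upper: 100.0
kIL17ST:
  value: 2.0
  unit: per day
  lower: 0.001
  upper: 100.0
lIL17ST:
  value: 0.7
  unit: a.u.
  lower: 0.01
  upper: 10.0
dIL17:
  value: 1.621
  unit: per day
  lower: 0.001
  upper: 100.0
kMIRp65:
  value: 2.532
  unit: per day
  lower: 0.001
  upper: 100.0
lMIRp65:
  value: 0.8
  unit: a.u.
  lower: 0.01
  upper: 10.0
kMIRpST:
  value: 0.488
  unit: per day
  lower: 0.001
  upper: 100.0
lMIRpST:
  value: 0.8
  unit: a.u.
  lower: 0.01
  upper: 10.0
dMIR:
  value: 4.5
  unit: per day
  lower: 0.001
  upper: 100.0
kGp0:
  value: 0.28
  unit: per day
  lower: 0.001
  upper: 100.0
kGp:
  value: 0.12
  unit: per day
  lower: 0.001
  upper: 100.0
lGpMIR:
  value: 1.0
  unit: a.u.
  lower: 0.01
  upper: 10.0
dGp:
  value: 0.4
  unit: per day
  lower: 0.001
  upper: 100.0
kI17R0:
  value: 0.03975
  unit: per day
  lower: 0.001
  upper: 100.0
kI17R:
  value: 0.715
  unit: per day
  lower: 0.001
  upper: 100.0
lI17RMIR:
  value: 1.0
  unit: a.u.
  lower: 0.01
  upper: 10.0
dI17R:
  value: 0.7548
  unit: per day
  lower: 0.001
  upper: 100.0
kAxi0:
  value: 0.039
  unit: per day
  lower: 0.001
  upper: 100.0
kAxi:
  value: 1.261
  unit: per day
  lower: 0.001
  upper: 100.0
lAxiMIR:
  value: 1.0
  unit: a.u.
  lower: 0.01
  upper: 10.0
dAxi:
  value: 1.3
  unit: per day
  lower: 0.001
  upper: 100.0
kLat0:
  value: 0.0075
  unit: per day
  lower: 0.001
  upper: 100.0
kLat:
  value: 0.2425
  unit: per day
  lower: 0.001
  upper: 100.0
lLatMIR:
  value: 1.0
  unit: a.u.
  lower: 0.01
  upper: 10.0
dLat:
  value: 0.25
  unit: per day
  lower: 0.001
  upper: 100.0
gammaGpMIR:
  value: 3.2
  unit: dimensionless
  lower: 0.01
  upper: 100.0
gammaI17RMIR:
  value: 2.007
  unit: dimensionless
  lower: 0.01
  upper: 100.0
gammaAxiMIR:
  value: 8.0
  unit: dimensionless
  lower: 0.01
  upper: 100.0
gammaLatMIR:
  value: 2.5
  unit: dimensionless
  lower: 0.01
  upper: 100.0
kBcat:
  value: 2.0
  unit: per day
  lower: 0.001
  upper: 100.0
lBcatAxi:
  value: 0.5
  unit: a.u.
  lower: 0.01
  upper: 10.0
dBcat:
  value: 1.0
  unit: per day
  lower: 0.001
  upper: 100.0
kYap:
  value: 2.0
  unit: per day
  lower: 0.001
  upper: 100.0
lYapLat:
  value: 0.5
  unit: a.u.
  lower: 0.01
  upper: 10.0
dYap:
  value: 1.0
  unit: per day
  lower: 0.001
  upper: 100.0
kProlif:
  value: 0.9365
  unit: per day
  lower: 0.001
  upper: 100.0
lNBcat:
  value: 0.2
  unit: a.u.
  lower: 0.01
  upper: 10.0
lNYap:
  value: 0.2
  unit: a.u.
  lower: 0.01
  upper: 10.0
kDamage:
  value: 2.224
  unit: per day
  lower: 0.001
  upper: 100.0
lNIL1:
  value: 1.396
  unit: a.u.
  lower: 0.01
  upper: 10.0
Nmax:
  value: 1.2
  unit: a.u.
  lower: 0.01
  upper: 10.0
Nbase:
  value: 1.0
  unit: a.u.
  lower: 0.01
  upper: 10.0
dN:
  value: 0.3759
  unit: per day
  lower: 0.001
  upper: 100.0
w0:
  value: 2.0
  unit: a.u.
  lower: 0.01
  upper: 10.0
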