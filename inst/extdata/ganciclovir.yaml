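# Ganciclovir / valganciclovir drug parameters.
# Internal units: mg, L, h. Per-parameter units are declared explicitly.
# clint_oat1 is the lumped basolateral uptake transporter ("OAT1"; OAT2/OAT3
# contributions are not separated). clint_oat1 and clint_met are starting
# values refined by calibrate_elimination() against fe_target and
# target_total_cl in the reference healthy subject.
molecular_weight: {value: 255.23, unit: g/mol}
fu_plasma: {value: 0.98, unit: fraction}          # 1-2% plasma protein binding
blood_plasma_ratio: {value: 1.0, unit: unitless}
ka: {value: 0.895, unit: 1/h}                      # oral valganciclovir
f_abs: {value: 0.60, unit: fraction}               # valganciclovir availability
clint_met: {value: 1.8, unit: L/h}                 # minor hepatic route
clint_oat1: {value: 5.5, unit: uL/min/10^6 cells}
clint_mate: {value: 60, unit: uL/min/10^6 cells}   # apical efflux, insensitive
passive_perm_clearance: {value: 0.0, unit: L/h}    # poor membrane permeability
fe_target: {value: 0.88, unit: fraction}           # excreted unchanged in urine
target_total_cl: {value: 15.0, unit: L/h}          # reference IV plasma CL
solubility_low: {value: 2600, unit: mg/L}          # aqueous solubility window
solubility_high: {value: 6000, unit: mg/L}
kp:                                                # tissue:plasma partition
  liver: 0.9
  kidney: 1.5
  muscle: 0.8
  adipose: 0.15
  rest: 0.88
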