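# Generic (synthetic, non-canonical) reference-human PBPK parameter set
# for HCN inhalation. Assembled from standard physiological reference
# tables; cyanide-specific constants set to round literature-scale
# values. Identical to fireCN::default_pbpk_params().
#
# Units: volumes L, flows L/min, k_met 1/min, body_weight kg,
# molecular_weight g/mol, molar_volume L/mol (25 C, 1 atm).
arterial: arterial
venous: venous
cardiac_output: 6.2
alveolar_ventilation: 5.4
blood_air_partition: 200.0
body_weight: 70.0
molecular_weight: 27.03
molar_volume: 24.45
blood:
  arterial: 1.8
  venous: 3.7
tissues:
  liver:
    volume: 1.82
    flow: 1.55
    partition: 1.0
    k_met: 0.35
  kidney:
    volume: 0.31
    flow: 1.18
    partition: 1.0
    k_met: 0.0
  muscle:
    volume: 28.0
    flow: 1.05
    partition: 1.0
    k_met: 0.0
  fat:
    volume: 13.3
    flow: 0.31
    partition: 0.25
    k_met: 0.0
  rich:
    volume: 3.0
    flow: 2.11
    partition: 1.0
    k_met: 0.0
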