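# Compound definition fixture (versioned): pathway targets, effect
# constants, and Cmax-based dose-to-serum mapping for the six modelled
# phytonutrients.
#
# SYNTHETIC STAND-INS: cmax_nM, reference_dose, max_dose and the
# ROS-scavenging potencies (k_scav) are representative literature-scale
# values chosen once as package defaults, not transcriptions of a primary
# pharmacokinetic source; the scavenging potencies implement the reported
# qualitative ordering (delphinidin, ellagic acid and malvidin strongest).
# Ellagic acid's dose axis is a concentration (uM) and its EC50 (b) is
# placed well below the serum reached at 80 uM so that its enzyme response
# plateaus beyond that dose. The Nrf2-axis amplitudes (a / emax) are the
# frozen output of fit_effect_constants against the per-compound
# enzyme-panel percent targets.
version: 1
compounds:
  cyanidin:
    targets: [ros_scavenging]
    cmax_nM: 100.0
    reference_dose: 100.0
    dose_unit: mg/day
    max_dose: 500.0
    effect_constants:
      k_scav: 0.001
  delphinidin:
    targets: [ros_scavenging, nrf2_activation]
    cmax_nM: 120.0
    reference_dose: 100.0
    dose_unit: mg/day
    max_dose: 500.0
    enzyme_target_percent: 120.0
    effect_constants:
      k_scav: 0.00283
      a: 95.7912036951528
      b: 150.0
  ellagic_acid:
    targets: [ros_scavenging, keap1_downregulation]
    cmax_nM: 500.0
    reference_dose: 80.0
    dose_unit: uM
    max_dose: 160.0
    enzyme_target_percent: 98.0
    effect_constants:
      k_scav: 0.0013
      emax: 0.8608272550296
      b: 2.0
  kaempferol:
    targets: [ros_scavenging, nrf2_degradation_inhibition]
    cmax_nM: 80.0
    reference_dose: 100.0
    dose_unit: mg/day
    max_dose: 400.0
    enzyme_target_percent: 3.0
    effect_constants:
      k_scav: 0.000875
      emax: 0.0871224270703
      b: 80.0
  malvidin:
    targets: [ros_scavenging, nrf2_activation]
    cmax_nM: 150.0
    reference_dose: 100.0
    dose_unit: mg/day
    max_dose: 500.0
    enzyme_target_percent: 25.0
    effect_constants:
      k_scav: 0.00127
      a: 1.3303346503129
      b: 190.0
  rutin:
    targets: [ros_scavenging, nrf2_activation]
    cmax_nM: 200.0
    reference_dose: 200.0
    dose_unit: mg/day
    max_dose: 600.0
    enzyme_target_percent: 40.0
    effect_constants:
      k_scav: 0.000667
      a: 2.5774786442029
      b: 150.0
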