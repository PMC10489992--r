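# Antioxidant-enzyme production model configuration.
# initial_concentrations: nM.
# Core Nrf2-cycle constants are fixed model choices; k_imp (nuclear import)
# is calibrated so that the saturating ceiling of the enzyme response over
# the compound lattice matches the reported combination response, and the
# per-enzyme synthesis constants (k0_*, k1_*) are the frozen output of
# calibrate_baselines against enzyme_baselines (basal and ARE-activated
# synthesis each carrying half of the baseline flux).
initial_concentrations:
  Maf: 4000.0
  Keap1: 2000.0
  Nrf2: 1800.0
  H2O2i: 1500.0
kinetic_constants:
  k_nrf2_syn: 0.1       # nM/s, Nrf2 synthesis
  k_bind: 0.00001       # 1/(nM s), Keap1-Nrf2 association
  k_unbind: 0.0001      # 1/s, complex dissociation
  k_rel: 0.0000001      # 1/(nM s), H2O2-stimulated Nrf2 release
  k_dKN: 0.0001         # 1/s, Keap1-mediated Nrf2 degradation
  k_imp: 0.001341432495       # 1/s, Nrf2 nuclear import (calibrated)
  k_dn: 0.0001          # 1/s, nuclear Nrf2 degradation
  k_nm: 0.000001        # 1/(nM s), Nrf2n-Maf association
  k_nmu: 0.001          # 1/s, Nrf2n-Maf dissociation
  k_dNM: 0.0001         # 1/s, complexed Nrf2 degradation (Maf recycled)
  k_h_src: 1.5          # nM/s, basal H2O2 source
  k_h_clr: 0.001        # 1/s, basal H2O2 clearance
  k0_CAT: 0.00042       # nM/s, basal synthesis (calibrated)
  k1_CAT: 0.000002007548846     # 1/s per nM complex, ARE-activated synthesis (calibrated)
  k_deg_CAT: 0.00002    # 1/s
  k0_HO1: 0.000112
  k1_HO1: 0.0000005353463589
  k_deg_HO1: 0.00002
  k0_SOD: 0.02791
  k1_SOD: 0.0001334064007
  k_deg_SOD: 0.00002
  k0_GPx: 0.15718
  k1_GPx: 0.0007513012561
  k_deg_GPx: 0.00002
enzyme_baselines:
  CAT: 42.0
  HO1: 11.2
  SOD: 2791.0
  GPx: 15718.0
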