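# Physical constants and frozen model coefficients (CGS units).
# Gas state is taken at airway-lumen ("body") conditions.
gas:
  temperature_K: 310.0
  viscosity_g_cm_s: 1.89e-4
  mean_free_path_um: 0.0712
  gravity_cm_s2: 981.0
  boltzmann_erg_K: 1.380649e-16
# Rat inhalability curve IF(d) = 1 - 1/(1 + exp(a - b*log(d_ae_um))),
# calibrated once so the two reference exposure aerosols (MMAD 2.74/GSD 2.8
# and MMAD 2.01/GSD 3.0) attain mass-weighted inhalable fractions of 0.745
# and 0.775 (see calibrate_inhalability()).
inhalability:
  rat:
    a: 1.779522383
    b: 0.6116964691
# Extrathoracic (head) filtration 1 - exp(-a*(d_ae_um^2 * Q_cm3_s)^b) per
# species/route, a calibrated once against the reference head deposition
# fractions (human nasal 51.3%, human oral 14.3% of inhaled; rat nose-only
# 34.5% of inhalable mass) at the resting flows of the standard scenarios
# (see calibrate_extrathoracic()). dead_space_cm3 is the extrathoracic
# airspace volume ahead of the trachea.
extrathoracic:
  human_nasal:
    a: 1.540578536e-2
    b: 0.5
  human_oral:
    a: 2.301935266e-5
    b: 1.0
  rat_nose-only:
    a: 3.584288854e-3
    b: 1.0
  dead_space_cm3:
    human: 50.0
    rat: 0.42
# Total alveolar (expanding) volume apportioned over pulmonary airways.
# Human value consistent with the near-total-capacity inflation of the
# embedded typical-path geometry; rat value resting functional volume.
lung:
  human_alveolar_volume_cm3: 3910.0
  rat_alveolar_volume_cm3: 4.0
  # settling-chamber scale of alveolus-stored air
  alveolus_diameter_cm:
    human: 0.028
    rat: 0.008
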