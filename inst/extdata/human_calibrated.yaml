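species: human
body_mass_kg: 70.0
flow_m3_s: 1.2e-05
tissues:
  body:
    mass_kg: 66.5
    specific_heat_J_kgC: 3500.0
    metabolic_fraction: 0.78
  head:
    mass_kg: 1.4
    specific_heat_J_kgC: 3600.0
    metabolic_fraction: 0.2
  neck:
    mass_kg: 1.0
    specific_heat_J_kgC: 3500.0
    metabolic_fraction: 0.02
blood_nodes:
  neck_art:
    volume_m3: 3.0e-05
    wall_conductance_W_C: 2.630242577435427
  head_blood:
    volume_m3: 0.00015
    wall_conductance_W_C: 8.0
  neck_ven:
    volume_m3: 3.0e-05
    wall_conductance_W_C: 14.956001348021962
  body_blood:
    volume_m3: 0.0043
    wall_conductance_W_C: 150.0
conductances:
  body_env: 3.3144437007008
  head_env: 0.836349950092891
  body_neck: 0.3
  neck_head: 0.1
  el_env: 0.3
  el_el: 0.2
  el1_neck: 2.0
  el2_neck: 2.0
basal_metabolic_kcal_day: 1200.0
environment_T_C: 23.0
blood:
  density_kg_m3: 1050.0
  specific_heat_J_kgC: 3800.0
collar:
  source_power_W: 60.0
  efficiency: 0.6
  n_elements: 2.0
  skin_floor_C: 5.0
  guard_band_C: 1.0
elements:
  mode: sink
  heat_capacity_J_C: 200.0
  env_coupling: first
provenance:
  species: literature-default
  body_mass_kg: literature-default
  flow_m3_s: literature-default
  tissues.body.mass_kg: literature-default
  tissues.body.specific_heat_J_kgC: literature-default
  tissues.body.metabolic_fraction: literature-default
  tissues.head.mass_kg: literature-default
  tissues.head.specific_heat_J_kgC: literature-default
  tissues.head.metabolic_fraction: literature-default
  tissues.neck.mass_kg: literature-default
  tissues.neck.specific_heat_J_kgC: literature-default
  tissues.neck.metabolic_fraction: literature-default
  blood_nodes.neck_art.volume_m3: literature-default
  blood_nodes.neck_art.wall_conductance_W_C: calibrated
  blood_nodes.head_blood.volume_m3: literature-default
  blood_nodes.head_blood.wall_conductance_W_C: literature-default
  blood_nodes.neck_ven.volume_m3: literature-default
  blood_nodes.neck_ven.wall_conductance_W_C: calibrated
  blood_nodes.body_blood.volume_m3: literature-default
  blood_nodes.body_blood.wall_conductance_W_C: literature-default
  conductances.body_env: calibrated
  conductances.head_env: calibrated
  conductances.body_neck: literature-default
  conductances.neck_head: literature-default
  conductances.el_env: literature-default
  conductances.el_el: literature-default
  conductances.el1_neck: literature-default
  conductances.el2_neck: literature-default
  basal_metabolic_kcal_day: literature-default
  environment_T_C: literature-default
  blood.density_kg_m3: literature-default
  blood.specific_heat_J_kgC: literature-default
  collar.source_power_W: literature-default
  collar.efficiency: literature-default
  collar.n_elements: literature-default
  collar.skin_floor_C: literature-default
  collar.guard_band_C: literature-default
  elements.mode: literature-default
  elements.heat_capacity_J_C: literature-default
  elements.env_coupling: literature-default
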