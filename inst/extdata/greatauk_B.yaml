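# Great auk year-round simulation, scenario B:
# resident near the breeding colony all year, staying at sea at night outside
# the breeding season (common-guillemot-like strategy). Values reconstructed
# from analog extant species; provenance tags mark assumptions.
scenario: B
description: >
  Resident at the colony year-round; stays at sea through the night when not
  constrained by breeding.
mass_g: 5000                 # provenance: assumed
bmr_method: mean
multiplier_family: Spheniscidae
assimilation_efficiency: 0.744
prey_energy_kj: 158
breeding_window:
  start_day: 121
  end_day: 181
breeding_budget:
  forage_h: 7
  on_water_h: 5
  on_land_h: 12
forage_target_h: 6
night_rule: on_water         # nights at sea outside breeding
jitter_sd_h: 0.0
locations:
  colony:
    latitude: 63.3
    sst_mean_c: 6.5
    sst_amplitude_c: 3.5
    sst_phase_day: 233
    air_mean_c: 4.5
    air_amplitude_c: 6.0
    air_phase_day: 212
    noise_sd_c: 0.4
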