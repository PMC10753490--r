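# Great auk year-round simulation, scenario C:
# southward migration (by swimming; the species was flightless) to a wintering
# ground in the Atlantic off Morocco, the southernmost location where great auk
# bones have been found (Atlantic-puffin-like dispersive strategy). Values
# reconstructed from analog extant species; provenance tags mark assumptions.
scenario: C
description: >
  Breeds at the Arctic colony, then swims to a Moroccan-Atlantic wintering
  ground for the non-breeding season, staying at sea at night.
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
night_rule: on_water
jitter_sd_h: 0.0
migration:                   # provenance: assumed (puffin-like autumn departure, spring return)
  depart_day: 244            # Sep 1: leaves colony waters
  outbound_days: 30
  return_day: 105            # Apr 15: back in colony waters
  inbound_days: 30
travel_budget:               # provenance: assumed; directed swimming costed as foraging-type activity
  forage_h: 10
  on_water_h: 14
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
  wintering:                 # provenance: assumed; Atlantic off Agadir, Morocco
    latitude: 31.0
    sst_mean_c: 19.0
    sst_amplitude_c: 2.5
    sst_phase_day: 250
    air_mean_c: 19.0
    air_amplitude_c: 4.0
    air_phase_day: 230
    noise_sd_c: 0.4
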