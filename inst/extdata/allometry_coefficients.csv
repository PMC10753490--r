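equation_id,quantity,a,b,mass_unit,output_unit,provenance,source_note
bmr_seabird,basal metabolic rate,2.30,0.774,g,kJ_per_day,reconstructed,all-seabird BMR allometry (Ellis & Gabrielsen 2002); converted to kJ per h internally
bmr_duck,basal metabolic rate,422.19,0.744,kg,kJ_per_day,reconstructed,wild waterfowl RMR allometry (Miller & Eadie 2006); converted to kJ per h internally
lct,lower critical temperature,47.17,-0.181,g,degC,reconstructed,avian lower critical temperature allometry (Kendeigh et al. 1977)
tc_in_water,thermal conductance fully submerged,2.42,-0.33,kg,kJ_per_h_per_degC_per_kg,reconstructed,aquatic-bird conductance; surface-to-volume scaling calibrated to heat-loss measurements in water (de Vries & van Eerden 1995)
tc_on_water,thermal conductance sitting on water,1.21,-0.33,kg,kJ_per_h_per_degC_per_kg,reconstructed,aquatic-bird conductance on the water surface; about half the submerged rate
tc_air,thermal conductance in air,0.55,-0.33,kg,kJ_per_h_per_degC_per_kg,reconstructed,aquatic-bird conductance in air; water conducts heat several-fold faster than air
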