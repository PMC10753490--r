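guild_id,flight_style,foraging_style,rests_on_water,rests_on_land
flap_glide_plunge_divers,flap-glide,plunge-diving,TRUE,TRUE
flap_glide_surface_feeders,flap-glide,surface-feeding,FALSE,TRUE
flap_foot_divers,flap,foot-propelled diving,TRUE,TRUE
flap_foot_divers_no_water_rest,flap,foot-propelled diving,FALSE,TRUE
flap_surface_feeders,flap,surface-feeding,TRUE,TRUE
flap_wing_divers,flap,wing-propelled diving,TRUE,TRUE
glide_surface_feeders,glide,surface-feeding,TRUE,TRUE
flightless_wing_divers,flightless,wing-propelled diving,TRUE,TRUE
flap_glide_wing_divers,flap-glide,wing-propelled diving,TRUE,TRUE
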