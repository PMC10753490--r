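family_group,guild_id,has_direct_multipliers,source_note
Alcidae,flap_wing_divers,TRUE,auks; flapping wing-propelled divers
Anatidae,flap_foot_divers,TRUE,sea ducks; flapping foot-propelled divers that rest on water
Laridae,flap_surface_feeders,TRUE,gulls and terns; flapping surface feeders
Stercorariidae,flap_surface_feeders,TRUE,skuas; flapping surface feeders
Fregatidae,flap_glide_surface_feeders,TRUE,frigatebirds; flap-gliding surface feeders that do not rest on water
Phalacrocoracidae,flap_foot_divers_no_water_rest,TRUE,cormorants and shags; foot-propelled divers roosting ashore
Diomedeidae,glide_surface_feeders,TRUE,albatrosses; gliding surface feeders
Spheniscidae,flightless_wing_divers,TRUE,penguins; flightless wing-propelled divers
Sulidae,flap_glide_plunge_divers,TRUE,gannets and boobies; flap-gliding plunge divers
Procellariidae A,flap_glide_surface_feeders,FALSE,fulmarine petrels / gadfly petrels / prions; guild assignment reconstructed
Procellariidae B,flap_wing_divers,FALSE,diving petrels; guild assignment reconstructed
Procellariidae C,flap_glide_wing_divers,FALSE,shearwaters; no measured family in this guild
Hydrobatidae,flap_surface_feeders,FALSE,northern storm petrels; guild assignment reconstructed
Oceanitidae,flap_surface_feeders,FALSE,southern storm petrels; guild assignment reconstructed
Phaethontidae,flap_glide_plunge_divers,FALSE,tropicbirds; guild assignment reconstructed
Pelecanidae,flap_glide_plunge_divers,FALSE,pelicans; guild assignment reconstructed
Gaviidae,flap_foot_divers,FALSE,divers/loons; guild assignment reconstructed
Podicipedidae,flap_foot_divers,FALSE,grebes; guild assignment reconstructed
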