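family_group,activity,multiplier,provenance,source_note
Alcidae,flight,31.0,printed,flapping flight with dive-adapted wings (murre flight-cost measurements)
Alcidae,forage,8.0,reconstructed,wing-propelled diving bouts incl. surface pauses (auk dive-cost literature)
Alcidae,on_water,2.7,reconstructed,resting on water; murre on-water resting metabolism
Alcidae,on_land,1.9,reconstructed,colony attendance resting/standing
Anatidae,flight,12.5,reconstructed,sea duck flapping flight (eider flight-cost estimates)
Anatidae,forage,5.5,reconstructed,foot-propelled diving bouts (eider/scoter diving metabolism)
Anatidae,on_water,2.2,reconstructed,resting on water
Anatidae,on_land,1.7,reconstructed,roosting ashore
Laridae,flight,7.0,reconstructed,gull/tern flapping flight
Laridae,forage,4.0,reconstructed,surface-feeding incl. search flight components
Laridae,on_water,1.8,reconstructed,resting on water
Laridae,on_land,1.5,reconstructed,loafing/roosting ashore
Stercorariidae,flight,5.5,reconstructed,skua flapping/soaring flight
Stercorariidae,forage,3.5,reconstructed,surface feeding and kleptoparasitic chases
Stercorariidae,on_water,1.8,reconstructed,resting on water
Stercorariidae,on_land,1.5,reconstructed,territory attendance
Fregatidae,flight,2.5,reconstructed,frigatebird soaring-dominated flight
Fregatidae,forage,3.0,reconstructed,aerial surface-snatching
Fregatidae,on_land,1.5,reconstructed,perch roosting (plumage not waterproof; never rests on water)
Phalacrocoracidae,flight,20.5,printed,cormorant flight with wings optimised for underwater propulsion
Phalacrocoracidae,forage,6.5,reconstructed,foot-propelled diving with wettable plumage (shag dive costs)
Phalacrocoracidae,on_land,1.7,reconstructed,roosting/wing-drying ashore
Diomedeidae,flight,2.2,printed,dynamic soaring; albatross heart-rate/DLW flight costs
Diomedeidae,forage,3.5,reconstructed,surface seizing incl. landings and take-offs
Diomedeidae,on_water,2.0,printed,resting on water
Diomedeidae,on_land,0.8,printed,colony attendance below resting baseline
Spheniscidae,forage,4.7,reconstructed,wing-propelled diving bouts (penguin heart-rate at-sea metabolism)
Spheniscidae,on_water,2.0,reconstructed,resting at the sea surface (penguin on-water resting metabolism)
Spheniscidae,on_land,1.4,reconstructed,standing/resting ashore (penguin colony metabolism)
Sulidae,flight,6.1,reconstructed,gannet flapping-gliding flight (DLW estimates)
Sulidae,forage,7.0,reconstructed,plunge-diving bouts incl. flight components
Sulidae,on_water,2.1,reconstructed,resting on water
Sulidae,on_land,1.6,reconstructed,colony attendance
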