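family_group,activity,donor_family,source_note
Procellariidae A,flight,Fregatidae,same guild (flap-gliding surface feeders)
Procellariidae A,forage,Fregatidae,same guild
Procellariidae A,on_land,Fregatidae,same guild
Procellariidae B,flight,Alcidae,same guild (flapping wing-propelled divers)
Procellariidae B,forage,Alcidae,same guild
Procellariidae B,on_water,Alcidae,same guild
Procellariidae B,on_land,Alcidae,same guild
Procellariidae C,flight,Diomedeidae,closely related flap-gliding family that rests on water
Procellariidae C,forage,Alcidae,other wing-propelled foragers
Procellariidae C,on_water,Diomedeidae,closely related flap-gliding family that rests on water
Procellariidae C,on_land,Diomedeidae,closely related flap-gliding family
Hydrobatidae,flight,Laridae,same guild (flapping surface feeders)
Hydrobatidae,forage,Laridae,same guild
Hydrobatidae,on_water,Laridae,same guild
Hydrobatidae,on_land,Laridae,same guild
Oceanitidae,flight,Laridae,same guild (flapping surface feeders)
Oceanitidae,forage,Laridae,same guild
Oceanitidae,on_water,Laridae,same guild
Oceanitidae,on_land,Laridae,same guild
Phaethontidae,flight,Sulidae,same guild (flap-gliding plunge divers)
Phaethontidae,forage,Sulidae,same guild
Phaethontidae,on_water,Sulidae,same guild
Phaethontidae,on_land,Sulidae,same guild
Pelecanidae,flight,Sulidae,same guild (flap-gliding plunge divers)
Pelecanidae,forage,Sulidae,same guild
Pelecanidae,on_water,Sulidae,same guild
Pelecanidae,on_land,Sulidae,same guild
Gaviidae,flight,Anatidae,same guild (flapping foot-propelled divers)
Gaviidae,forage,Anatidae,same guild
Gaviidae,on_water,Anatidae,same guild
Gaviidae,on_land,Anatidae,same guild
Podicipedidae,flight,Anatidae,same guild (flapping foot-propelled divers)
Podicipedidae,forage,Anatidae,same guild
Podicipedidae,on_water,Anatidae,same guild
Podicipedidae,on_land,Anatidae,same guild
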