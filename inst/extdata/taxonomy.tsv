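common_name	scientific_name	family	genus	gene_prefix
Freshwater crocodile	Crocodylus johnsoni	Crocodilidae	Crocodylus	Crjo
Philippine crocodile	Crocodylus mindorensis	Crocodilidae	Crocodylus	Crmi
Nile crocodile	Crocodylus niloticus	Crocodilidae	Crocodylus	Crni
American crocodile	Crocodylus acutus	Crocodilidae	Crocodylus	Crac
Mugger crocodile	Crocodylus palustris	Crocodilidae	Crocodylus	Crpa
Dwarf crocodile	Osteolaemus tetraspis	Crocodilidae	Osteolaemus	Oste
Siamese crocodile	Crocodylus siamensis	Crocodilidae	Crocodylus	Crsi
Slender-snouted crocodile	Mecistops cataphractus	Crocodilidae	Mecistops	Meca
Orinoco crocodile	Crocodylus intermedius	Crocodilidae	Crocodylus	Crin
Cuban crocodile	Crocodylus rhombifer	Crocodilidae	Crocodylus	Crrh
New Guinea crocodile	Crocodylus novaeguineae	Crocodilidae	Crocodylus	Crno
Saltwater crocodile	Crocodylus porosus	Crocodilidae	Crocodylus	Crpo
Morelet's crocodile	Crocodylus moreletii	Crocodilidae	Crocodylus	Crmo
American alligator	Alligator mississippiensis	Alligatoridae	Alligator	Almi
Chinese alligator	Alligator sinensis	Alligatoridae	Alligator	Alsi
Cuvier's dwarf caiman	Paleosuchus palpebrosus	Alligatoridae	Paleosuchus	Papa
Spectacled caiman	Caiman crocodylus	Alligatoridae	Caiman	Cacr
Broad-snouted caiman	Caiman latirostris	Alligatoridae	Caiman	Cala
Yacare caiman	Caiman yacare	Alligatoridae	Caiman	Caya
Black caiman	Melanosuchus niger	Alligatoridae	Melanosuchus	Meni
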