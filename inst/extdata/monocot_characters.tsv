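# Character states for gene gain/duplication/pseudogenization/loss mapping
# on the monocot tree fixture (synthetic transcription of the published
# figure annotations; binary 0/1 plus a multistate rps19 history column).
# rps19_pseudogene: the duplicated rps19 copy is a pseudogene.
# ndhF_ycf1_overlap: pseudo-ycf1 overlaps ndhF.
# rps19_duplication: a second rps19 copy (intact or degraded) is present.
# rps19_state: none / dup / pseudo / lost.
taxon	rps19_duplication	rps19_pseudogene	rps19_loss	ndhF_ycf1_overlap	rps19_state
Amborella	0	0	0	0	none
Nuphar	0	0	0	0	none
Acorus	0	0	0	0	none
Colocasia	0	0	0	0	none
Cymbidium	1	0	0	0	dup
Bismarckia	1	0	0	1	dup
Calamus	1	0	0	1	dup
Chamaedorea	1	0	0	1	dup
Cocos	1	1	0	1	pseudo
Elaeis	1	0	0	1	dup
Phoenix	1	0	0	1	dup
Pseudophoenix	1	0	0	1	dup
Dasypogon	1	0	0	1	dup
Kingia	1	0	0	1	dup
Typha	1	0	0	0	dup
Alpinia	1	0	0	0	dup
Heliconia	1	1	0	0	pseudo
Musa	1	0	0	0	dup
Xiphidium	0	0	1	0	lost
Chloranthus	0	0	0	1	none
Drimys	0	0	0	1	none
Magnolia	0	0	0	0	none
Piper	0	0	0	0	none
Ceratophyllum	0	0	1	0	lost
Nandina	1	1	0	0	pseudo
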