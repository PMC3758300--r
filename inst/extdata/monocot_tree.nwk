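(Amborella,(Nuphar,((Ceratophyllum,Nandina),((Acorus,(Colocasia,(Cymbidium,(((Calamus,(Phoenix,(Bismarckia,(Pseudophoenix,(Chamaedorea,(Cocos,Elaeis)))))),(Dasypogon,Kingia)),(Typha,((Musa,(Alpinia,Heliconia)),Xiphidium)))))),(Chloranthus,((Drimys,Piper),Magnolia))))));
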