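species_id,compound_id,evidence
quelea_like,lutein,diet
quelea_like,zeaxanthin,diet
quelea_like,beta-carotene,diet
quelea_like,lutein,plumage
quelea_like,zeaxanthin,plumage
quelea_like,alpha-doradexanthin,plumage
quelea_like,astaxanthin,plumage
quelea_like,adonirubin,plumage
quelea_like,canthaxanthin,plumage
quelea_like,echinenone,plasma
woodpecker_like,lutein,diet
woodpecker_like,zeaxanthin,diet
woodpecker_like,beta-carotene,diet
woodpecker_like,lutein,plumage
woodpecker_like,zeaxanthin,plumage
woodpecker_like,alpha-doradexanthin,plumage
woodpecker_like,astaxanthin,plumage
woodpecker_like,adonirubin,plumage
woodpecker_like,canthaxanthin,plumage
woodpecker_like,echinenone,plasma
lutein_only,lutein,diet
lutein_only,lutein,plumage
lutein_only,canary-xanthophyll-A,plumage
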