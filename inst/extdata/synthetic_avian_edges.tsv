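reaction_id	substrate	product
r01	beta-carotene	echinenone
r02	echinenone	canthaxanthin
r03	canthaxanthin	adonirubin
r04	adonirubin	astaxanthin
r05	zeaxanthin	adonixanthin
r06	adonixanthin	astaxanthin
r07	beta-cryptoxanthin	3-hydroxyechinenone
r08	3-hydroxyechinenone	adonirubin
r09	lutein	alpha-doradexanthin
r10	lutein	3-dehydrolutein
r11	3-dehydrolutein	canary-xanthophyll-A
r12	beta-carotene	beta-cryptoxanthin
r13	beta-cryptoxanthin	zeaxanthin
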