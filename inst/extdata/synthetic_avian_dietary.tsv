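compound_id
lutein
zeaxanthin
beta-carotene
beta-cryptoxanthin
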