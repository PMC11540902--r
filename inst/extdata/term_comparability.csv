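term,countable
live,TRUE
skins,TRUE
bodies,TRUE
trophies,TRUE
eggs,TRUE
shells,TRUE
meat,FALSE
skin_pieces,FALSE
leather_products,FALSE
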