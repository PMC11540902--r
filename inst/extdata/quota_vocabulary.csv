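token,dimension,canonical
live,term,live
live individuals,term,live
live specimens,term,live
skins,term,skins
skin,term,skins
whole skins,term,skins
skin pieces,term,skin_pieces
small leather pieces,term,leather_products
leather products,term,leather_products
skin products,term,leather_products
meat,term,meat
bodies,term,bodies
trophies,term,trophies
hunting trophies,term,trophies
eggs,term,eggs
shells,term,shells
tails,term,skin_pieces
sides,term,skin_pieces
bellies,term,skin_pieces
consumption,term,meat
wild,source,wild
wild-taken,source,wild
wild taken,source,wild
wild-sourced,source,wild
wild-caught,source,wild
captive-bred,source,captive
captive bred,source,captive
captive,source,captive
f1,source,f1
f1 captive,source,f1
captive-born,source,f1
ranched,source,ranched
ranching,source,ranched
commercial,purpose,commercial
personal,purpose,personal
hunting,purpose,hunting
hunting trophy,purpose,hunting
scientific,purpose,scientific
zoo,purpose,zoo
breeding,purpose,breeding
sabah,region,sabah
sarawak,region,sarawak
peninsular malaysia,region,peninsular_malaysia
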