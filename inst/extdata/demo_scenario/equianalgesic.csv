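opioid,route_class,ome_multiplier,is_methadone
morphine,oral,1,FALSE
oxycodone,oral,1.5,FALSE
hydromorphone,oral,4,FALSE
morphine,parenteral,3,FALSE
fentanyl,transdermal,100,FALSE
methadone,oral,4,TRUE
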