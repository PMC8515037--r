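name,log_p
"Trans-β-ocimene",4.8
"γ-Elemene",4.8
"α-Copaene",5.4
"(-)-Isocomene",5.0
"β-Copaene",5.4
"Aromandendrene",5.2
"β-Sesquiphellandrene",5.8
"Naphthalene, 1,2,3,4,4a,7-hexahydro-1,6-dimethyl-4-(1-methylethyl)-",4.9
"Germacrene D",5.3
"α-Funebrene",5.5
"Bicyclogermacrene",5.2
"α-Farnesene",5.9
"(+)-δ-cadinene",5.6
"Espatulenol",3.9
"(-)-α-bisabolol oxide B",3.2
"Cedr-8-ene",5.7
"Chamazulene",5.1
"Bisabolol oxide A",3.0
"Hexahydrofarnesyl acetone",5.1
"(Z)-ene-yne-dicycloether",2.8
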