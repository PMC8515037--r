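name,cas,content_pct,retention_index,log_p
"Trans-β-ocimene","3779-61-1",2.728,1049.212,
"γ-Elemene","29873-99-2",3.882,1343.234,
"α-Copaene","003856-25-5",0.756,1382.972,
"(-)-Isocomene","065372-78-3",0.943,1396.072,
"β-Copaene","018252-44-3",2.639,1427.655,
"Aromandendrene","000489-39-4",0.653,1448.85,
"β-Sesquiphellandrene","020307-83-9",18.527,1467.285,
"Naphthalene, 1,2,3,4,4a,7-hexahydro-1,6-dimethyl-4-(1-methylethyl)-","16728-99-7",0.661,1487.56,
"Germacrene D","023986-74-5",4.835,1494.01,
"α-Funebrene","50894-66-1",1.452,1499.08,
"Bicyclogermacrene","100762-46-7",4.822,1509.228,
"α-Farnesene","000502-61-4",6.573,1515.053,
"(+)-δ-cadinene","000483-76-1",0.86,1533.014,
"Espatulenol","006750-60-3",2.127,1597.092,
"(-)-α-bisabolol oxide B","026184-88-3",9.46,1672.963,
"Cedr-8-ene","000469-61-4",9.606,1718.242,
"Chamazulene","000529-05-5",6.398,1952.009,
"Bisabolol oxide A","022567-36-8",12.071,1970.864,
"Hexahydrofarnesyl acetone","000502-69-2",0.888,2043.486,
"(Z)-ene-yne-dicycloether","004575-53-5",6.074,1906.516,
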