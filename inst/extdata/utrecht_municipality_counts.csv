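municipality,expected_n,actual_n
Bunnik,367,536
Bunschoten,819,1051
De Bilt,1148,1369
Houten,2011,1993
IJsselstein,991,1317
Leusden,828,1062
Nijkerk,1422,1784
Renswoude,231,305
Scherpenzeel,505,460
Stichtse Vecht,2460,2473
Utrecht,13461,18420
Utrechtse Heuvelrug,1239,1503
Woudenberg,566,590
Zeist,2313,2531
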