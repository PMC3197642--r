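code	name
0	Central Chile (Maule, O'Higgins)
1	Cumbres Calchaquies
2	Atacama
3	Arica
4	Prepuna of Catamarca
5	Central Bolivia
6	Araucania, Bio-Bio
7	Payunia
8	Central Rio Negro
9	Payunia and Central Chile
A	Prepuna of Salta and Jujuy
B	Atacama (Chile)
C	Puna of Jujuy
D	Cuyo
E	Atacama and Coquimbo
F	Maule
G	Atacama and Puna of Bolivia
H	Northern Atacama (Chile)
I	Los Lagos (Chile)
J	Central Monte (La Rioja)
K	Central Chile (Metropolitana, O'Higgins)
L	Central Patagonia (Santa Cruz)
M	Northern Patagonia
N	Central Patagonia (Rio Negro)
O	Coquimbo
P	Central Chile (Coquimbo)
Q	Payunia and Monte Central
R	Central Monte (Mendoza)
S	Prepuna (Jujuy and Bolivia)
T	Austral Patagonia
U	Sierras Subandinas and Cumbres Calchaquies
V	Prepuna and Monte Boreal
W	Coastal Central Peru
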