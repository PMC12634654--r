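country,continent
US,Americas
CA,Americas
BR,Americas
MX,Americas
AR,Americas
CO,Americas
CL,Americas
PE,Americas
JP,Asia
CN,Asia
IN,Asia
KR,Asia
TH,Asia
ID,Asia
PH,Asia
VN,Asia
MY,Asia
SG,Asia
TW,Asia
HK,Asia
IL,Asia
SA,Asia
TR,Asia
AE,Asia
PK,Asia
BD,Asia
GB,Europe
FR,Europe
DE,Europe
IT,Europe
ES,Europe
NL,Europe
BE,Europe
CH,Europe
SE,Europe
NO,Europe
DK,Europe
FI,Europe
PL,Europe
AT,Europe
PT,Europe
IE,Europe
GR,Europe
CZ,Europe
HU,Europe
RO,Europe
RU,Europe
UA,Europe
ZA,Africa
NG,Africa
EG,Africa
KE,Africa
MA,Africa
TN,Africa
GH,Africa
ET,Africa
AU,Oceania
NZ,Oceania
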