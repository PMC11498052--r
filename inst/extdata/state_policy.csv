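state,region,expansion_date,generous_pre_aca
AL,South,,FALSE
AK,West,2015-09-01,FALSE
AZ,West,2014-01-01,TRUE
AR,South,2014-01-01,FALSE
CA,West,2014-01-01,TRUE
CO,West,2014-01-01,FALSE
CT,Northeast,2014-01-01,FALSE
DE,South,2014-01-01,TRUE
DC,South,2014-01-01,TRUE
FL,South,,FALSE
GA,South,,FALSE
HI,West,2014-01-01,TRUE
ID,West,,FALSE
IL,Midwest,2014-01-01,FALSE
IN,Midwest,2015-02-01,FALSE
IA,Midwest,2014-01-01,FALSE
KS,Midwest,,FALSE
KY,South,2014-01-01,FALSE
LA,South,2016-07-01,FALSE
ME,Northeast,,FALSE
MD,South,2014-01-01,FALSE
MA,Northeast,2014-01-01,FALSE
MI,Midwest,2014-04-01,FALSE
MN,Midwest,2014-01-01,FALSE
MS,South,,FALSE
MO,Midwest,,FALSE
MT,West,2016-01-01,FALSE
NE,Midwest,,FALSE
NV,West,2014-01-01,FALSE
NH,Northeast,2014-08-15,FALSE
NJ,Northeast,2014-01-01,FALSE
NM,West,2014-01-01,FALSE
NY,Northeast,2014-01-01,TRUE
NC,South,,FALSE
ND,Midwest,2014-01-01,FALSE
OH,Midwest,2014-01-01,FALSE
OK,South,,FALSE
OR,West,2014-01-01,FALSE
PA,Northeast,2015-01-01,FALSE
RI,Northeast,2014-01-01,FALSE
SC,South,,FALSE
SD,Midwest,,FALSE
TN,South,,FALSE
TX,South,,FALSE
UT,West,,FALSE
VT,Northeast,2014-01-01,TRUE
VA,South,,FALSE
WA,West,2014-01-01,FALSE
WV,South,2014-01-01,FALSE
WI,Midwest,,FALSE
WY,West,,FALSE
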