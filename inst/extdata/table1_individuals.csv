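individual_id,sex,parity,maternal_id,observation_hours,life_stage
AL,female,primiparous,MAL,12.34,infant
AM,female,multiparous,MAM,14.2,infant
AR,female,primiparous,MAR,13.55,infant
AZ,female,multiparous,MAZ,15.08,infant
BA,female,multiparous,MP02,12.12,infant
BB,male,multiparous,MP04,24.51,infant
BO,male,primiparous,MBO,9.45,infant
BU,male,primiparous,MBU,12.88,infant
CF,female,multiparous,MP02,30.12,infant
CH,female,multiparous,MP03,28.4,infant
CL,male,multiparous,MCL,19.77,infant
DA,male,multiparous,MP04,11.02,infant
DO,male,multiparous,MP05,10.56,infant
EL,female,multiparous,MP03,11.93,infant
EM,female,primiparous,MEM,12.77,infant
FI,female,primiparous,MFI,13.3,juvenile
GA,female,primiparous,MGA,9.91,juvenile
HA,female,primiparous,MHA,10.64,juvenile
HD,male,multiparous,MHD,21.46,infant
IV,male,multiparous,MIV,8.75,infant
JO,female,primiparous,MJO,20.15,infant
KE,male,multiparous,MKE,23.12,infant
KO,female,multiparous,MP05,22.3,infant
LU,male,multiparous,MP07,10.23,infant
MA,male,primiparous,MMA,12.41,infant
MI,male,multiparous,MP06,14.85,infant
MO,male,multiparous,MP07,11.28,infant
NA1,female,multiparous,MP01,37.24,infant
NI,male,multiparous,MNI,9.08,infant
OF,male,multiparous,MP01,17.52,juvenile
OT,male,primiparous,MOT,11.69,infant
PE,female,multiparous,MPE,16.41,infant
RU,female,primiparous,MRU,2.72,juvenile
SA,female,multiparous,MSA,12.81,infant
TO,male,multiparous,MP06,26.08,infant
ZW,male,multiparous,MZW,18.93,infant
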