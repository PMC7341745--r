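res,chi1,chi2,chi3,chi4
SER,-65,,,
SER,180,,,
SER,62,,,
CYS,-65,,,
CYS,180,,,
CYS,62,,,
THR,-60,,,
THR,180,,,
THR,60,,,
VAL,175,,,
VAL,-60,,,
VAL,64,,,
LEU,-65,175,,
LEU,180,65,,
LEU,-85,65,,
LEU,180,180,,
ILE,-65,170,,
ILE,-60,-60,,
ILE,62,170,,
ILE,180,165,,
MET,-65,180,180,
MET,-65,-65,-70,
MET,180,180,180,
MET,180,65,75,
MET,62,180,75,
PRO,,,,
PHE,-65,90,,
PHE,180,80,,
PHE,62,90,,
PHE,-65,-30,,
TYR,-65,90,,
TYR,180,80,,
TYR,62,90,,
TYR,-65,-30,,
TRP,-65,95,,
TRP,180,-105,,
TRP,62,-90,,
TRP,-65,-5,,
ASP,-70,-15,,
ASP,180,15,,
ASP,62,15,,
ASN,-65,-20,,
ASN,180,30,,
ASN,62,30,,
ASN,-65,120,,
GLU,-65,180,-10,
GLU,180,180,0,
GLU,62,180,0,
GLU,-65,-65,-40,
GLN,-65,180,-25,
GLN,180,180,0,
GLN,62,180,20,
GLN,-65,-65,-40,
HIS,-65,-70,,
HIS,180,170,,
HIS,62,-75,,
HIS,-65,165,,
LYS,-65,180,180,180
LYS,180,180,180,180
LYS,62,180,180,180
LYS,-65,-65,180,180
LYS,180,65,180,180
ARG,-65,180,180,180
ARG,180,180,180,180
ARG,62,180,180,180
ARG,-65,-65,180,180
ARG,180,65,65,180
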