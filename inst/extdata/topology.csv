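res,atom,p1,p2,p3,length,angle,tor_base,tor_offset
ALA,CB,CA,N,C,1.530,110.5,,122.5
SER,CB,CA,N,C,1.530,110.5,,122.5
SER,OG,CB,CA,N,1.417,110.8,chi1,0
CYS,CB,CA,N,C,1.530,110.5,,122.5
CYS,SG,CB,CA,N,1.808,113.8,chi1,0
THR,CB,CA,N,C,1.540,110.5,,122.5
THR,OG1,CB,CA,N,1.433,109.6,chi1,0
THR,CG2,CB,CA,N,1.521,110.5,chi1,-120.0
VAL,CB,CA,N,C,1.540,110.5,,122.5
VAL,CG1,CB,CA,N,1.521,110.5,chi1,0
VAL,CG2,CB,CA,N,1.521,110.5,chi1,122.5
LEU,CB,CA,N,C,1.530,110.5,,122.5
LEU,CG,CB,CA,N,1.530,116.3,chi1,0
LEU,CD1,CG,CB,CA,1.521,110.7,chi2,0
LEU,CD2,CG,CB,CA,1.521,110.7,chi2,122.5
ILE,CB,CA,N,C,1.540,110.5,,122.5
ILE,CG1,CB,CA,N,1.530,110.4,chi1,0
ILE,CG2,CB,CA,N,1.521,110.5,chi1,-122.5
ILE,CD1,CG1,CB,CA,1.513,113.8,chi2,0
MET,CB,CA,N,C,1.530,110.5,,122.5
MET,CG,CB,CA,N,1.520,114.1,chi1,0
MET,SD,CG,CB,CA,1.803,112.7,chi2,0
MET,CE,SD,CG,CB,1.791,100.9,chi3,0
PRO,CB,CA,N,C,1.543,104.7,,118.8
PRO,CG,CB,CA,N,1.543,105.1,,23.8
PRO,CD,CG,CB,CA,1.544,105.1,,0.0
PHE,CB,CA,N,C,1.530,110.5,,122.5
PHE,CG,CB,CA,N,1.502,113.8,chi1,0
PHE,CD1,CG,CB,CA,1.384,120.8,chi2,0
PHE,CD2,CG,CB,CA,1.384,120.8,chi2,180.0
PHE,CE1,CD1,CG,CB,1.382,121.0,,180.0
PHE,CE2,CD2,CG,CB,1.382,121.0,,180.0
PHE,CZ,CE1,CD1,CG,1.382,119.5,,0.0
TYR,CB,CA,N,C,1.530,110.5,,122.5
TYR,CG,CB,CA,N,1.512,113.8,chi1,0
TYR,CD1,CG,CB,CA,1.389,120.8,chi2,0
TYR,CD2,CG,CB,CA,1.389,120.8,chi2,180.0
TYR,CE1,CD1,CG,CB,1.382,121.1,,180.0
TYR,CE2,CD2,CG,CB,1.382,121.1,,180.0
TYR,CZ,CE1,CD1,CG,1.378,119.6,,0.0
TYR,OH,CZ,CE1,CD1,1.376,119.9,,180.0
TRP,CB,CA,N,C,1.530,110.5,,122.5
TRP,CG,CB,CA,N,1.498,113.6,chi1,0
TRP,CD1,CG,CB,CA,1.365,126.9,chi2,0
TRP,CD2,CG,CB,CA,1.433,126.6,chi2,180.0
TRP,NE1,CD1,CG,CB,1.374,110.2,,180.0
TRP,CE2,NE1,CD1,CG,1.370,109.0,,0.0
TRP,CE3,CD2,CG,CD1,1.398,133.9,,180.0
TRP,CZ2,CE2,NE1,CD1,1.394,122.4,,180.0
TRP,CZ3,CE3,CD2,CG,1.382,118.6,,180.0
TRP,CH2,CZ2,CE2,NE1,1.368,117.5,,180.0
ASP,CB,CA,N,C,1.530,110.5,,122.5
ASP,CG,CB,CA,N,1.516,112.6,chi1,0
ASP,OD1,CG,CB,CA,1.249,118.4,chi2,0
ASP,OD2,CG,CB,CA,1.249,118.4,chi2,180.0
ASN,CB,CA,N,C,1.530,110.5,,122.5
ASN,CG,CB,CA,N,1.516,112.6,chi1,0
ASN,OD1,CG,CB,CA,1.231,120.8,chi2,0
ASN,ND2,CG,CB,CA,1.328,116.4,chi2,180.0
GLU,CB,CA,N,C,1.530,110.5,,122.5
GLU,CG,CB,CA,N,1.520,114.1,chi1,0
GLU,CD,CG,CB,CA,1.516,112.6,chi2,0
GLU,OE1,CD,CG,CB,1.249,118.4,chi3,0
GLU,OE2,CD,CG,CB,1.249,118.4,chi3,180.0
GLN,CB,CA,N,C,1.530,110.5,,122.5
GLN,CG,CB,CA,N,1.520,114.1,chi1,0
GLN,CD,CG,CB,CA,1.516,112.6,chi2,0
GLN,OE1,CD,CG,CB,1.231,120.8,chi3,0
GLN,NE2,CD,CG,CB,1.328,116.4,chi3,180.0
HIS,CB,CA,N,C,1.530,110.5,,122.5
HIS,CG,CB,CA,N,1.504,113.8,chi1,0
HIS,ND1,CG,CB,CA,1.378,122.7,chi2,0
HIS,CD2,CG,CB,CA,1.354,131.2,chi2,180.0
HIS,CE1,ND1,CG,CB,1.321,109.3,,180.0
HIS,NE2,CE1,ND1,CG,1.310,108.4,,0.0
LYS,CB,CA,N,C,1.530,110.5,,122.5
LYS,CG,CB,CA,N,1.520,114.1,chi1,0
LYS,CD,CG,CB,CA,1.520,111.3,chi2,0
LYS,CE,CD,CG,CB,1.520,111.3,chi3,0
LYS,NZ,CE,CD,CG,1.489,111.9,chi4,0
ARG,CB,CA,N,C,1.530,110.5,,122.5
ARG,CG,CB,CA,N,1.520,114.1,chi1,0
ARG,CD,CG,CB,CA,1.520,111.3,chi2,0
ARG,NE,CD,CG,CB,1.461,112.0,chi3,0
ARG,CZ,NE,CD,CG,1.329,124.2,chi4,0
ARG,NH1,CZ,NE,CD,1.326,120.0,,0.0
ARG,NH2,CZ,NE,CD,1.326,120.0,,180.0
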