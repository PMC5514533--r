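# Default partial charges (electron-charge units) for the electrostatic
# term, force-field-inspired values for standard residues and
# deoxyribonucleotides. Keys are residue name + PDB atom name. Atoms absent
# from this table are skipped (with a warning) by the electrostatic scorer.
#
# Protein backbone (all 20 amino acids share these entries per residue).
ALA N -0.47
ALA H 0.31
ALA C 0.51
ALA O -0.51
ARG N -0.47
ARG H 0.31
ARG C 0.51
ARG O -0.51
ASN N -0.47
ASN H 0.31
ASN C 0.51
ASN O -0.51
ASP N -0.47
ASP H 0.31
ASP C 0.51
ASP O -0.51
CYS N -0.47
CYS H 0.31
CYS C 0.51
CYS O -0.51
GLN N -0.47
GLN H 0.31
GLN C 0.51
GLN O -0.51
GLU N -0.47
GLU H 0.31
GLU C 0.51
GLU O -0.51
GLY N -0.47
GLY H 0.31
GLY C 0.51
GLY O -0.51
HIS N -0.47
HIS H 0.31
HIS C 0.51
HIS O -0.51
ILE N -0.47
ILE H 0.31
ILE C 0.51
ILE O -0.51
LEU N -0.47
LEU H 0.31
LEU C 0.51
LEU O -0.51
LYS N -0.47
LYS H 0.31
LYS C 0.51
LYS O -0.51
MET N -0.47
MET H 0.31
MET C 0.51
MET O -0.51
PHE N -0.47
PHE H 0.31
PHE C 0.51
PHE O -0.51
PRO N -0.29
PRO C 0.51
PRO O -0.51
SER N -0.47
SER H 0.31
SER C 0.51
SER O -0.51
THR N -0.47
THR H 0.31
THR C 0.51
THR O -0.51
TRP N -0.47
TRP H 0.31
TRP C 0.51
TRP O -0.51
TYR N -0.47
TYR H 0.31
TYR C 0.51
TYR O -0.51
VAL N -0.47
VAL H 0.31
VAL C 0.51
VAL O -0.51
# Polar side chains.
SER OG -0.66
SER HG 0.43
THR OG1 -0.66
THR HG1 0.43
CYS SG -0.23
CYS HG 0.16
TYR OH -0.54
TYR HH 0.43
ASN OD1 -0.55
ASN ND2 -0.62
ASN HD21 0.32
ASN HD22 0.32
GLN OE1 -0.55
GLN NE2 -0.62
GLN HE21 0.32
GLN HE22 0.32
ASP CG 0.62
ASP OD1 -0.76
ASP OD2 -0.76
GLU CD 0.62
GLU OE1 -0.76
GLU OE2 -0.76
LYS NZ -0.30
LYS HZ1 0.33
LYS HZ2 0.33
LYS HZ3 0.33
ARG NE -0.70
ARG HE 0.44
ARG CZ 0.64
ARG NH1 -0.80
ARG NH2 -0.80
ARG HH11 0.46
ARG HH12 0.46
ARG HH21 0.46
ARG HH22 0.46
MET SD -0.09
# Aromatic rings (used directly and via the pi-system sums).
PHE CG 0.00
PHE CD1 -0.115
PHE CD2 -0.115
PHE CE1 -0.115
PHE CE2 -0.115
PHE CZ -0.115
PHE HD1 0.115
PHE HD2 0.115
PHE HE1 0.115
PHE HE2 0.115
PHE HZ 0.115
TYR CG 0.00
TYR CD1 -0.115
TYR CD2 -0.115
TYR CE1 -0.115
TYR CE2 -0.115
TYR CZ 0.11
TYR HD1 0.115
TYR HD2 0.115
TYR HE1 0.115
TYR HE2 0.115
TRP CG -0.03
TRP CD1 0.035
TRP CD2 0.055
TRP NE1 -0.61
TRP HE1 0.38
TRP CE2 0.13
TRP CE3 -0.115
TRP CZ2 -0.115
TRP CZ3 -0.115
TRP CH2 -0.115
HIS CG 0.22
HIS ND1 -0.36
HIS HD1 0.32
HIS CD2 0.10
HIS CE1 0.25
HIS NE2 -0.70
HIS HE2 0.32
# DNA backbone (shared across the four nucleotides).
DA P 1.17
DA OP1 -0.77
DA OP2 -0.77
DA O5' -0.50
DA O4' -0.36
DA O3' -0.52
DA HO3' 0.44
DC P 1.17
DC OP1 -0.77
DC OP2 -0.77
DC O5' -0.50
DC O4' -0.36
DC O3' -0.52
DC HO3' 0.44
DG P 1.17
DG OP1 -0.77
DG OP2 -0.77
DG O5' -0.50
DG O4' -0.36
DG O3' -0.52
DG HO3' 0.44
DT P 1.17
DT OP1 -0.77
DT OP2 -0.77
DT O5' -0.50
DT O4' -0.36
DT O3' -0.52
DT HO3' 0.44
# Adenine.
DA N9 -0.03
DA C8 0.20
DA H8 0.16
DA N7 -0.62
DA C5 0.07
DA C6 0.69
DA N6 -0.90
DA H61 0.41
DA H62 0.41
DA N1 -0.76
DA C2 0.50
DA H2 0.05
DA N3 -0.74
DA C4 0.43
# Guanine.
DG N9 0.05
DG C8 0.14
DG H8 0.16
DG N7 -0.57
DG C5 0.20
DG C6 0.48
DG O6 -0.57
DG N1 -0.51
DG H1 0.35
DG C2 0.74
DG N2 -0.92
DG H21 0.41
DG H22 0.41
DG N3 -0.66
DG C4 0.18
# Cytosine.
DC N1 -0.05
DC C2 0.75
DC O2 -0.65
DC N3 -0.78
DC C4 0.82
DC N4 -0.95
DC H41 0.42
DC H42 0.43
DC C5 -0.50
DC H5 0.19
DC C6 -0.01
DC H6 0.23
# Thymine.
DT N1 -0.02
DT C2 0.57
DT O2 -0.59
DT N3 -0.43
DT H3 0.34
DT C4 0.52
DT O4 -0.56
DT C5 0.00
DT C7 -0.23
DT H71 0.08
DT H72 0.08
DT H73 0.08
DT C6 -0.22
DT H6 0.26
[pi_atoms]
PHE CG CD1 CD2 CE1 CE2 CZ
TYR CG CD1 CD2 CE1 CE2 CZ
TRP CG CD1 CD2 NE1 CE2 CE3 CZ2 CZ3 CH2
HIS CG ND1 CD2 CE1 NE2
DA N9 C8 N7 C5 C6 N1 C2 N3 C4
DG N9 C8 N7 C5 C6 N1 C2 N3 C4
DC N1 C2 N3 C4 C5 C6
DT N1 C2 N3 C4 C5 C6
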