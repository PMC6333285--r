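# synthetic hand-written cubic SF4 dictionary (monomer-library dialect)
data_comp_list
loop_
_chem_comp.id
_chem_comp.name
_chem_comp.group
SF4  'IRON/SULFUR CLUSTER'  non-polymer

data_comp_SF4
loop_
_chem_comp_bond.comp_id
_chem_comp_bond.atom_id_1
_chem_comp_bond.atom_id_2
_chem_comp_bond.type
_chem_comp_bond.value_dist
_chem_comp_bond.value_dist_esd
SF4   FE1  S2  single  2.135  0.020
SF4   FE1  S3  single  2.135  0.020
SF4   FE1  S4  single  2.135  0.020
SF4   FE2  S1  single  2.135  0.020
SF4   FE2  S3  single  2.135  0.020
SF4   FE2  S4  single  2.135  0.020
SF4   FE3  S1  single  2.135  0.020
SF4   FE3  S2  single  2.135  0.020
SF4   FE3  S4  single  2.135  0.020
SF4   FE4  S1  single  2.135  0.020
SF4   FE4  S2  single  2.135  0.020
SF4   FE4  S3  single  2.135  0.020

loop_
_chem_comp_angle.comp_id
_chem_comp_angle.atom_id_1
_chem_comp_angle.atom_id_2
_chem_comp_angle.atom_id_3
_chem_comp_angle.value_angle
_chem_comp_angle.value_angle_esd
SF4  FE2  S1   FE3  90.0  0.87
SF4  FE2  S1   FE4  90.0  0.87
SF4  FE3  S1   FE4  90.0  0.87
SF4  FE1  S2   FE3  90.0  0.87
SF4  FE1  S2   FE4  90.0  0.87
SF4  FE3  S2   FE4  90.0  0.87
SF4  FE1  S3   FE2  90.0  0.87
SF4  FE1  S3   FE4  90.0  0.87
SF4  FE2  S3   FE4  90.0  0.87
SF4  FE1  S4   FE2  90.0  0.87
SF4  FE1  S4   FE3  90.0  0.87
SF4  FE2  S4   FE3  90.0  0.87
SF4  S2   FE1  S3   90.0  1.24
SF4  S2   FE1  S4   90.0  1.24
SF4  S3   FE1  S4   90.0  1.24
SF4  S1   FE2  S3   90.0  1.24
SF4  S1   FE2  S4   90.0  1.24
SF4  S3   FE2  S4   90.0  1.24
SF4  S1   FE3  S2   90.0  1.24
SF4  S1   FE3  S4   90.0  1.24
SF4  S2   FE3  S4   90.0  1.24
SF4  S1   FE4  S2   90.0  1.24
SF4  S1   FE4  S3   90.0  1.24
SF4  S2   FE4  S3   90.0  1.24

loop_
_chem_comp_chir.comp_id
_chem_comp_chir.id
_chem_comp_chir.atom_id_centre
_chem_comp_chir.atom_id_1
_chem_comp_chir.atom_id_2
_chem_comp_chir.atom_id_3
_chem_comp_chir.volume_sign
SF4  chir_1  FE1  S2  S3  S4  negative
SF4  chir_2  FE2  S1  S3  S4  positive
SF4  chir_3  FE3  S1  S2  S4  negative
SF4  chir_4  FE4  S1  S2  S3  positive
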