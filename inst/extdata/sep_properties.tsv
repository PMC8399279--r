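property	residues
hydrophobicity_polar	RKEDQN
hydrophobicity_neutral	GASTPHY
hydrophobicity_hydrophobic	CLVIMFW
vdw_volume_small	GASTPDC
vdw_volume_medium	NVEQIL
vdw_volume_large	MHKFRYW
polarity_low	LIFWCMVY
polarity_medium	PATGS
polarity_high	HQRKNED
polarizability_low	GASDT
polarizability_medium	CPNVEQIL
polarizability_high	KMHFRYW
charge_positive	KR
charge_neutral	ANCQGHILMFPSTWYV
charge_negative	DE
ss_helix	EALMQKRH
ss_strand	VIYCWFT
ss_coil	GNPSD
sa_buried	ALFCGIVW
sa_exposed	RKQEND
sa_intermediate	MSPTHY
aromatic	FHWY
aliphatic	ILV
tiny	ACGST
sulfur_containing	CM
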