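id	name	formula	charge	mass
sodium	Sodium	Na	1	22.99
potassium	Potassium	K	1	39.098
lithium	Lithium	Li	1	6.94
ammonium	Ammonium	NH4	1	18.039
calcium	Calcium	Ca	2	40.078
magnesium	Magnesium	Mg	2	24.305
zinc	Zinc	Zn	2	65.38
chloride	Chloride	Cl	-1	35.45
bromide	Bromide	Br	-1	79.904
iodide	Iodide	I	-1	126.904
fluoride	Fluoride	F	-1	18.998
nitrate	Nitrate	NO3	-1	62.004
sulfate	Sulfate	SO4	-2	96.056
hydrogensulfate	Hydrogen sulfate	HSO4	-1	97.064
phosphate	Phosphate	PO4	-3	94.97
acetate	Acetate	C2H3O2	-1	59.044
formate	Formate	CHO2	-1	45.017
mesylate	Methanesulfonate	CH3SO3	-1	95.092
besylate	Benzenesulfonate	C6H5SO3	-1	157.163
tosylate	p-Toluenesulfonate	C7H7SO3	-1	171.19
trifluoroacetate	Trifluoroacetate	C2F3O2	-1	113.014
maleate	Hydrogen maleate	C4H3O4	-1	115.064
fumarate	Hydrogen fumarate	C4H3O4	-1	115.064
tartrate	Hydrogen tartrate	C4H5O6	-1	149.078
citrate	Dihydrogen citrate	C6H7O7	-1	191.115
oxalate	Hydrogen oxalate	C2HO4	-1	89.026
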