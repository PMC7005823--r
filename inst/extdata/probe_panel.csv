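sku,name,category,application
N1148,NBD cholesterol,Lipid metabolism and trafficking,Sterol lipids
D3922,BODIPY 493,Lipid metabolism and trafficking,Neutral lipids
H34475,HCS LipidTOX Green,Lipid metabolism and trafficking,Neutral lipids
D3921,BODIPY 505,Lipid metabolism and trafficking,Neutral lipids
D3821,BODIPY FL C16,Lipid metabolism and trafficking,Fatty acyls
D3822,BODIPY FL C12,Lipid metabolism and trafficking,Fatty acyls
N3786,NBD C6-HPC,Lipid metabolism and trafficking,Glycerophospholipids
V12390,BODIPY FL vinblastine,Drug conjugate,Tubulin staining
Q2001,BODIPY FL C5,Lipid metabolism and trafficking,Fatty acyls
Q2002,BODIPY FL C12-sphingomyelin,Lipid metabolism and trafficking,Sphingolipids
Q2003,BODIPY FL C5-HPC,Lipid metabolism and trafficking,Glycerophospholipids
Q2004,NBD C6-ceramide,Lipid metabolism and trafficking,Sphingolipids
Q2005,Phen Green FL diacetate,Ion concentration,Heavy metal indicator
Q2006,Lipid probe placeholder 1,Lipid metabolism and trafficking,Phospholipids
Q2007,Lipid probe placeholder 2,Lipid metabolism and trafficking,Sterol lipids
Q2008,Lipid probe placeholder 3,Lipid metabolism and trafficking,Sphingolipids
Q2009,Lipid probe placeholder 4,Lipid metabolism and trafficking,Fatty acyls
Q2010,Lipid probe placeholder 5,Lipid metabolism and trafficking,Neutral lipids
Q2011,Lipid probe placeholder 6,Lipid metabolism and trafficking,Glycerophospholipids
Q2012,Organelle probe placeholder 1,Organelle morphology,Lysosomes
Q2013,Organelle probe placeholder 2,Organelle morphology,Mitochondria
Q2014,Organelle probe placeholder 3,Organelle morphology,Endoplasmic reticulum
Q2015,Organelle probe placeholder 4,Organelle morphology,Golgi apparatus
Q2016,Organelle probe placeholder 5,Organelle morphology,Early endosomes
Q2017,Organelle probe placeholder 6,Organelle morphology,Peroxisomes
Q2018,Organelle probe placeholder 7,Organelle morphology,Autophagosomes
Q2019,Organelle probe placeholder 8,Organelle morphology,Nucleoli
Q2020,Ion probe placeholder 1,Ion concentration,Calcium
Q2021,Ion probe placeholder 2,Ion concentration,Zinc
Q2022,Ion probe placeholder 3,Ion concentration,pH (cytosolic)
Q2023,Ion probe placeholder 4,Ion concentration,pH (lysosomal)
Q2024,Ion probe placeholder 5,Ion concentration,Magnesium
Q2025,Ion probe placeholder 6,Ion concentration,Sodium
Q2026,Ion probe placeholder 7,Ion concentration,Potassium
Q2027,Stress probe placeholder 1,Cellular stress,Reactive oxygen species
Q2028,Stress probe placeholder 2,Cellular stress,Glutathione
Q2029,Stress probe placeholder 3,Cellular stress,Hypoxia
Q2030,Stress probe placeholder 4,Cellular stress,Apoptosis (caspase)
Q2031,Stress probe placeholder 5,Cellular stress,Membrane asymmetry
Q2032,Membrane probe placeholder 1,Membrane dynamics,Plasma membrane
Q2033,Membrane probe placeholder 2,Membrane dynamics,Membrane potential
Q2034,Membrane probe placeholder 3,Membrane dynamics,Endocytosis
Q2035,Drug conjugate placeholder 1,Drug conjugate,Actin staining
Q2036,Drug conjugate placeholder 2,Drug conjugate,Microtubule dynamics
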