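# Default chemical-quality partition of litter carbon into the four labile
# compound groups (A acid-hydrolyzeable, W water-soluble, E ethanol-soluble,
# N non-soluble).  Editable configuration: rows must sum to 1.  Values are
# rounded defaults in the range reported by published boreal litter-chemistry
# compilations used with Yasso07-type models; they are NOT measurements from
# any single study.
species	component	A	W	E	N
spruce	foliage	0.51	0.13	0.08	0.28
pine	foliage	0.52	0.12	0.09	0.27
deciduous	foliage	0.40	0.17	0.09	0.34
spruce	branches	0.66	0.03	0.02	0.29
pine	branches	0.66	0.03	0.02	0.29
deciduous	branches	0.65	0.04	0.02	0.29
spruce	stem	0.66	0.03	0.02	0.29
pine	stem	0.66	0.03	0.02	0.29
deciduous	stem	0.65	0.04	0.02	0.29
spruce	stump	0.66	0.03	0.02	0.29
pine	stump	0.66	0.03	0.02	0.29
deciduous	stump	0.65	0.04	0.02	0.29
spruce	coarse_roots	0.66	0.03	0.02	0.29
pine	coarse_roots	0.66	0.03	0.02	0.29
deciduous	coarse_roots	0.65	0.04	0.02	0.29
spruce	fine_roots	0.52	0.15	0.06	0.27
pine	fine_roots	0.52	0.15	0.06	0.27
deciduous	fine_roots	0.52	0.15	0.06	0.27
ground_veg	moss	0.41	0.37	0.05	0.17
ground_veg	lichen	0.56	0.26	0.04	0.14
ground_veg	herbs	0.46	0.35	0.06	0.13
ground_veg	shrubs	0.49	0.27	0.06	0.18
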