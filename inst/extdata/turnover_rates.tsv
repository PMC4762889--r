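species	component	rate
spruce	foliage	0.143
pine	foliage	0.33
deciduous	foliage	1
spruce	branches	0.0125
pine	branches	0.027
deciduous	branches	0.025
spruce	coarse_roots	0.0125
pine	coarse_roots	0.027
deciduous	coarse_roots	0.025
spruce	fine_roots	0.6
pine	fine_roots	0.6
deciduous	fine_roots	0.6
ground_veg	moss_above	0.33
ground_veg	lichen_above	0.1
ground_veg	herbs_above	1
ground_veg	shrubs_above	0.25
ground_veg	herbs_below	0.33
ground_veg	shrubs_below	0.33
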