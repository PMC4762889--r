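# Rule parameters for constructing the historical (pre-simulation) litter
# series from the first-inventory state of each plot.  All biomass values in
# kg C m^-2 (total tree biomass); rates are per 5-year inventory cycle.
mature_change_rate: 0.10      # per-cycle biomass growth used to back-project stands older than 34 y
prior_litter_scale: 0.5       # tree-biomass scale applied before a land-use change
harvest_age:                  # recommended harvest age by site productivity class
  low: 120
  medium: 100
  high: 80
mature_biomass:               # stand biomass at recommended harvest age
  spruce:    {low: 4.0, medium: 6.5, high: 9.0}
  pine:      {low: 3.5, medium: 5.5, high: 7.5}
  deciduous: {low: 2.5, medium: 4.0, high: 5.5}
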