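stratum,mean,se
Savannah,0.642,0.111
Shrub,1.837,0.589
Grassland-Tropical/Subtropical,1.887,0.304
Grassland-Temperate,4.224,0.518
Grassland-Cool Temperate,4.504,1.337
Grassland-Tundra,4.804,1.188
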