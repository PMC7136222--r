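carbon_domain,phylogeny,mean,se
Tropical,angiosperm,0.454,0.003
Tropical,mixed,0.452,0.004
Tropical,gymnosperm,0.450,0.008
Subtropical/Mediterranean,angiosperm,0.465,0.006
Subtropical/Mediterranean,mixed,0.478,0.008
Subtropical/Mediterranean,gymnosperm,0.484,0.009
Temperate,angiosperm,0.472,0.005
Temperate,mixed,0.483,0.006
Temperate,gymnosperm,0.489,0.006
Boreal,angiosperm,0.488,0.013
Boreal,mixed,0.480,0.011
Boreal,gymnosperm,0.476,0.009
Global,angiosperm,0.471,0.011
Global,mixed,0.476,0.016
Global,gymnosperm,0.479,0.012
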