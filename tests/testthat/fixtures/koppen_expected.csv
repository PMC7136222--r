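kg_code,kg_class,grassland_class,carbon_domain
1,Af,Tropical/Subtropical,Tropical
2,Am,Tropical/Subtropical,Tropical
3,As,Tropical/Subtropical,Tropical
4,Aw,Tropical/Subtropical,Tropical
5,BSh,Temperate,Subtropical/Mediterranean
6,BSk,Temperate,Temperate
7,BWh,Temperate,Subtropical/Mediterranean
8,BWk,Temperate,Temperate
9,Cfa,Temperate,Subtropical/Mediterranean
10,Cfb,Temperate,Temperate
11,Cfc,Temperate,Temperate
12,Csa,Temperate,Subtropical/Mediterranean
13,Csb,Temperate,Temperate
14,Csc,Temperate,Temperate
15,Cwa,Temperate,Subtropical/Mediterranean
16,Cwb,Temperate,Subtropical/Mediterranean
17,Cwc,Temperate,Temperate
18,Dfa,Cool Temperate,Temperate
19,Dfb,Cool Temperate,Temperate
20,Dfc,Tundra,Boreal
21,Dfd,Tundra,Boreal
22,Dsa,Cool Temperate,Temperate
23,Dsb,Cool Temperate,Temperate
24,Dsc,Cool Temperate,Boreal
25,Dsd,Cool Temperate,Boreal
26,Dwa,Cool Temperate,Temperate
27,Dwb,Cool Temperate,Temperate
28,Dwc,Tundra,Boreal
29,Dwd,Tundra,Boreal
30,EF,Tundra,Boreal
31,ET,Tundra,Boreal
32,Ocean,Tropical/Subtropical,Global
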