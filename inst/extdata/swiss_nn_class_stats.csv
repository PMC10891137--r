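class,name,sensitivity,specificity
1,Industry,0.96,0.99
2,Building,0.90,0.99
3,Special urban,0.65,0.97
4,Urban green,0.64,0.98
5,Horticulture,0.84,0.98
6,Arable,0.91,1.00
7,Grassland,0.83,0.98
8,Alpine grassland,0.76,0.99
9,Forest,0.97,1.00
10,Brush,0.89,0.98
11,Trees,0.79,0.96
12,Unproductive vegetation,0.46,0.98
13,Bare land,0.85,0.98
14,Glacier,0.66,0.98
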