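class,name,epoch,YF,EQF
1,Cultivated land,2000,2.12,2.11
2,Forest,2000,1.18,1.35
3,Grassland,2000,0.81,0.47
4,Water,2000,1.27,0.35
5,Built up,2000,0,0
6,Deserted land,2000,0,0
1,Cultivated land,2010,2.21,2.39
2,Forest,2010,1.18,1.24
3,Grassland,2010,0.81,0.51
4,Water,2010,1.27,0.41
5,Built up,2010,0,0
6,Deserted land,2010,0,0
1,Cultivated land,2020,2.02,2.50
2,Forest,2020,1.18,1.28
3,Grassland,2020,0.81,0.46
4,Water,2020,1.27,0.37
5,Built up,2020,0,0
6,Deserted land,2020,0,0
1,Cultivated land,2030,2.02,2.50
2,Forest,2030,1.18,1.28
3,Grassland,2030,0.81,0.46
4,Water,2030,1.27,0.37
5,Built up,2030,0,0
6,Deserted land,2030,0,0
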