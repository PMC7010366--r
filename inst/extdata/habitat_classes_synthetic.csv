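class_id,name,national_cover_ha,removable
1,Broadleaved woodland,1300000,TRUE
2,Coniferous woodland,1200000,TRUE
3,Arable and horticulture,4500000,TRUE
4,Improved grassland,5000000,TRUE
5,Rough grassland,450000,TRUE
6,Neutral grassland,150000,TRUE
7,Calcareous grassland,100000,TRUE
8,Acid grassland,700000,TRUE
9,Fen marsh and swamp,200000,TRUE
10,Heather,600000,TRUE
11,Heather grassland,400000,TRUE
16,Freshwater,250000,FALSE
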