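code,name,group
20,shrubs,SHRUBS
30,herbaceous_vegetation,SHRUBS
90,herbaceous_wetland,SHRUBS
40,cropland,CROPLAND
60,bare_sparse_vegetation,SPARSE
50,urban,NONVEGETATED
70,snow_ice,NONVEGETATED
80,permanent_water,NONVEGETATED
100,moss_lichen,NONVEGETATED
200,open_sea,NONVEGETATED
111,closed_forest_evergreen_needle,FOREST
112,closed_forest_evergreen_broad,FOREST
113,closed_forest_deciduous_needle,FOREST
114,closed_forest_deciduous_broad,FOREST
115,closed_forest_mixed,FOREST
116,closed_forest_unknown,FOREST
121,open_forest_evergreen_needle,FOREST
122,open_forest_evergreen_broad,FOREST
123,open_forest_deciduous_needle,FOREST
124,open_forest_deciduous_broad,FOREST
125,open_forest_mixed,FOREST
126,open_forest_unknown,FOREST
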