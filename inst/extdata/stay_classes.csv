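group,state,trend,class
SPARSE,NOVEG,INCREASING,OVERNIGHT
SPARSE,NOVEG,CONSTANT,OVERNIGHT
SPARSE,NOVEG,DECREASING,OVERNIGHT
SPARSE,LOWEST,INCREASING,SHORT
SPARSE,LOWEST,CONSTANT,SHORT
SPARSE,LOWEST,DECREASING,SHORT
SPARSE,LOWER,INCREASING,SHORT
SPARSE,LOWER,CONSTANT,SHORT
SPARSE,LOWER,DECREASING,SHORT
SPARSE,DENSE,INCREASING,SHORT
SPARSE,DENSE,CONSTANT,SHORT
SPARSE,DENSE,DECREASING,SHORT
SPARSE,HIGHER,INCREASING,SHORT
SPARSE,HIGHER,CONSTANT,SHORT
SPARSE,HIGHER,DECREASING,SHORT
SPARSE,HIGHEST,INCREASING,SHORT
SPARSE,HIGHEST,CONSTANT,SHORT
SPARSE,HIGHEST,DECREASING,SHORT
SHRUBS,NOVEG,INCREASING,OVERNIGHT
SHRUBS,NOVEG,CONSTANT,OVERNIGHT
SHRUBS,NOVEG,DECREASING,OVERNIGHT
SHRUBS,LOWEST,INCREASING,SHORT
SHRUBS,LOWEST,CONSTANT,SHORT
SHRUBS,LOWEST,DECREASING,SHORT
SHRUBS,LOWER,INCREASING,SHORT
SHRUBS,LOWER,CONSTANT,SHORT
SHRUBS,LOWER,DECREASING,SHORT
SHRUBS,DENSE,INCREASING,MEDIUM
SHRUBS,DENSE,CONSTANT,MEDIUM
SHRUBS,DENSE,DECREASING,SHORT
SHRUBS,HIGHER,INCREASING,MEDIUM
SHRUBS,HIGHER,CONSTANT,MEDIUM
SHRUBS,HIGHER,DECREASING,SHORT
SHRUBS,HIGHEST,INCREASING,MEDIUM
SHRUBS,HIGHEST,CONSTANT,MEDIUM
SHRUBS,HIGHEST,DECREASING,SHORT
CROPLAND,NOVEG,INCREASING,OVERNIGHT
CROPLAND,NOVEG,CONSTANT,OVERNIGHT
CROPLAND,NOVEG,DECREASING,OVERNIGHT
CROPLAND,LOWEST,INCREASING,SHORT
CROPLAND,LOWEST,CONSTANT,SHORT
CROPLAND,LOWEST,DECREASING,SHORT
CROPLAND,LOWER,INCREASING,MEDIUM
CROPLAND,LOWER,CONSTANT,MEDIUM
CROPLAND,LOWER,DECREASING,SHORT
CROPLAND,DENSE,INCREASING,MEDIUM
CROPLAND,DENSE,CONSTANT,MEDIUM
CROPLAND,DENSE,DECREASING,SHORT
CROPLAND,HIGHER,INCREASING,LONG
CROPLAND,HIGHER,CONSTANT,LONG
CROPLAND,HIGHER,DECREASING,MEDIUM
CROPLAND,HIGHEST,INCREASING,LONG
CROPLAND,HIGHEST,CONSTANT,LONG
CROPLAND,HIGHEST,DECREASING,MEDIUM
FOREST,NOVEG,INCREASING,OVERNIGHT
FOREST,NOVEG,CONSTANT,OVERNIGHT
FOREST,NOVEG,DECREASING,OVERNIGHT
FOREST,LOWEST,INCREASING,SHORT
FOREST,LOWEST,CONSTANT,SHORT
FOREST,LOWEST,DECREASING,SHORT
FOREST,LOWER,INCREASING,MEDIUM
FOREST,LOWER,CONSTANT,MEDIUM
FOREST,LOWER,DECREASING,SHORT
FOREST,DENSE,INCREASING,MEDIUM
FOREST,DENSE,CONSTANT,MEDIUM
FOREST,DENSE,DECREASING,SHORT
FOREST,HIGHER,INCREASING,MEDIUM
FOREST,HIGHER,CONSTANT,MEDIUM
FOREST,HIGHER,DECREASING,SHORT
FOREST,HIGHEST,INCREASING,MEDIUM
FOREST,HIGHEST,CONSTANT,MEDIUM
FOREST,HIGHEST,DECREASING,SHORT
NONVEGETATED,NOVEG,INCREASING,OVERNIGHT
NONVEGETATED,NOVEG,CONSTANT,OVERNIGHT
NONVEGETATED,NOVEG,DECREASING,OVERNIGHT
NONVEGETATED,LOWEST,INCREASING,OVERNIGHT
NONVEGETATED,LOWEST,CONSTANT,OVERNIGHT
NONVEGETATED,LOWEST,DECREASING,OVERNIGHT
NONVEGETATED,LOWER,INCREASING,OVERNIGHT
NONVEGETATED,LOWER,CONSTANT,OVERNIGHT
NONVEGETATED,LOWER,DECREASING,OVERNIGHT
NONVEGETATED,DENSE,INCREASING,OVERNIGHT
NONVEGETATED,DENSE,CONSTANT,OVERNIGHT
NONVEGETATED,DENSE,DECREASING,OVERNIGHT
NONVEGETATED,HIGHER,INCREASING,OVERNIGHT
NONVEGETATED,HIGHER,CONSTANT,OVERNIGHT
NONVEGETATED,HIGHER,DECREASING,OVERNIGHT
NONVEGETATED,HIGHEST,INCREASING,OVERNIGHT
NONVEGETATED,HIGHEST,CONSTANT,OVERNIGHT
NONVEGETATED,HIGHEST,DECREASING,OVERNIGHT
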