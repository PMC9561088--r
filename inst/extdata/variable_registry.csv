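name,group,kind,units,description
bio1,climatic,continuous,degC,Annual mean temperature
bio2,climatic,continuous,degC,Mean diurnal range (mean of monthly max temp - min temp)
bio3,climatic,continuous,degC,Isothermality (bio2/bio7 x 100)
bio4,climatic,continuous,degC,Temperature seasonality (standard deviation x 100)
bio5,climatic,continuous,degC,Maximum temperature of warmest month
bio6,climatic,continuous,degC,Minimum temperature of coldest month
bio7,climatic,continuous,degC,Temperature annual range (bio5 - bio6)
bio8,climatic,continuous,degC,Mean temperature of wettest quarter
bio9,climatic,continuous,degC,Mean temperature of driest quarter
bio10,climatic,continuous,degC,Mean temperature of warmest quarter
bio11,climatic,continuous,degC,Mean temperature of coldest quarter
bio12,climatic,continuous,mm,Annual precipitation
bio13,climatic,continuous,mm,Precipitation of wettest month
bio14,climatic,continuous,mm,Precipitation of driest month
bio15,climatic,continuous,mm,Precipitation seasonality (coefficient of variation)
bio16,climatic,continuous,mm,Precipitation of wettest quarter
bio17,climatic,continuous,mm,Precipitation of driest quarter
bio18,climatic,continuous,mm,Precipitation of warmest quarter
bio19,climatic,continuous,mm,Precipitation of coldest quarter
WatVapPress01,climatic,continuous,kPa,Water vapour pressure of the wettest month
WatVapPress02,climatic,continuous,kPa,Water vapour pressure of the driest month
Elevation,climatic,continuous,m,Metres above sea level
Soil_pH,soil,continuous,pH,Soil pH (x10 in H2O)
Soil_CatEx_Capacity,soil,continuous,cmol/kg,Soil cation exchange capacity at 0 m depth
Soil_Bulk_D,soil,continuous,kg/m3,Soil bulk density at 0 m depth
Soil_Organic_Carbon,soil,continuous,g/kg,Soil organic carbon at 0 m depth
Soil_Clay,soil,continuous,percent,Soil clay content (mass fraction) at 0 m depth
Soil_Silt,soil,continuous,percent,Soil silt content (mass fraction) at 0 m depth
Soil_Sand,soil,continuous,percent,Soil sand content (mass fraction) at 0 m depth
Soil_Water_Capacity,soil,continuous,mm/m,Soil total available water capacity per 1 m soil depth
Forest,vegetation_landcover,continuous,percent,Forest cover
Grass_Land,vegetation_landcover,continuous,percent,Grass/shrub land cover
Cult_L,vegetation_landcover,continuous,percent,Land used for agriculture (cultivated land)
Crop_Dominance,vegetation_landcover,categorical,category,Crop dominance (major crops)
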