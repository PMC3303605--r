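year,dimension,category,total
2000,total,total,5772650
2000,sex,male,2994930
2000,sex,female,2777720
2000,age_group,0-4,387340
2000,age_group,5-14,762910
2000,age_group,15-24,1068940
2000,age_group,25-34,1230500
2000,age_group,35-44,900940
2000,age_group,45-54,645210
2000,age_group,55-64,384130
2000,age_group,65+,392690
2000,residential_status,urban,3046230
2000,residential_status,rural,2726420
2000,nationality,Han,5025790
2000,nationality,minority,746860
2000,education,tertiary,404200
2000,education,senior secondary,778740
2000,education,junior secondary,1587680
2000,education,primary,2030030
2000,education,other,496910
2000,education,under 6,475080
2005,total,total,6085700
2005,sex,male,3115270
2005,sex,female,2970430
2005,age_group,0-4,365120
2005,age_group,5-14,719130
2005,age_group,15-24,1088360
2005,age_group,25-34,1280240
2005,age_group,35-44,953170
2005,age_group,45-54,704260
2005,age_group,55-64,449010
2005,age_group,65+,526410
2005,residential_status,urban,3532750
2005,residential_status,rural,2552950
2005,nationality,Han,5265350
2005,nationality,minority,820350
2005,education,tertiary,455700
2005,education,senior secondary,973360
2005,education,junior secondary,1688170
2005,education,primary,1994600
2005,education,other,521040
2005,education,under 6,452830
2010,total,total,6355960
2010,sex,male,3253620
2010,sex,female,3102340
2010,age_group,0-4,338980
2010,age_group,5-14,712930
2010,age_group,15-24,1117380
2010,age_group,25-34,1316000
2010,age_group,35-44,1001060
2010,age_group,45-54,756680
2010,age_group,55-64,488140
2010,age_group,65+,624790
2010,residential_status,urban,3886030
2010,residential_status,rural,2469930
2010,nationality,Han,5462370
2010,nationality,minority,893590
2010,education,tertiary,507290
2010,education,senior secondary,1178330
2010,education,junior secondary,1837500
2010,education,primary,1928280
2010,education,other,481770
2010,education,under 6,422790
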