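year,salt_land_km2,water_body_km2,female,male,total
2012,103.24,434.56,142,108,250
2013,135.14,603.33,225,156,381
2014,185,406.40,75,40,115
2015,178,389.25,560,375,935
2016,229,330.14,784,497,1281
2017,345,280.56,1136,1017,2153
2018,343.6,260.3,1076,1010,2086
2019,189.70,540.9,1225,1115,2340
2020,111.51,654.85,1155,770,1925
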