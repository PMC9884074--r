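criterion,group,weight,s_first,s_total
age_group,demographic,0.12,0.051,0.054
population_density,demographic,0.048,0.061,0.068
hypertension,demographic,0.34,0.157,0.164
land_use,demographic,0.04,0.013,0.018
vegetation,demographic,0.025,0.042,0.028
aspect,land_surface,0.015,0.009,0.012
slope,land_surface,0.015,0.083,0.046
salt_center_distance,climatological,0.177,0.182,0.198
moisture,climatological,0.055,0.152,0.148
wind_direction,climatological,0.151,0.132,0.141
wind_speed,climatological,0.0038,0.006,0.009
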