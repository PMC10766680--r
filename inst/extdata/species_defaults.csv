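species,deciduous,min_active_layer_cm,bark_coef,resprout_prob,growth_rate_cm_yr,temp_optimum_c,temp_tolerance_c,maturity_height_cm,max_height_cm,seeds_per_year,release_frac,dispersal_sd_m,max_age_yr,background_mortality,seed_rain_per_m2_yr
Dahurian larch,TRUE,20,0.006,0.25,30,12,6,200,1400,40,0.5,20,400,0.015,0.02
Cajander larch,TRUE,20,0.0055,0.2,26,11,5,200,1350,30,0.5,20,400,0.015,0.002
Siberian larch,TRUE,20,0.005,0.15,28,13,5,200,1400,35,0.5,22,400,0.015,0.005
Siberian spruce,FALSE,200,0.002,0,20,13,4,250,1300,30,0.5,15,350,0.02,0.004
Scots pine,FALSE,100,0.004,0,25,14,4,250,1400,30,0.5,25,350,0.018,0.004
Siberian pine,FALSE,200,0.003,0,18,12,4,300,1300,25,0.5,18,450,0.018,0.003
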