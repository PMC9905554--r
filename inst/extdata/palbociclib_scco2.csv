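temperature_K,pressure_MPa,co2_density_kg_m3,mole_fraction,mass_solubility_g_L,std_y,expanded_uncertainty_y
308,12,769,3.91e-06,0.03057653,1.2e-07,2.7e-07
308,15,817,5.01e-06,0.041624148,2.4e-07,5.3e-07
308,18,849,5.52e-06,0.047657644,2.1e-07,4.7e-07
308,21,875,6.27e-06,0.055790688,1.1e-07,3.4e-07
308,24,896,6.97e-06,0.063507821,1.2e-07,3.6e-07
308,27,914,9.14e-06,0.084953204,2.1e-07,5.6e-07
318,12,661,2.21e-06,0.014855186,1e-07,2.2e-07
318,15,744,3.49e-06,0.026404824,1.5e-07,3.3e-07
318,18,791,4.19e-06,0.033703556,1.2e-07,3e-07
318,21,824,7.38e-06,0.061840099,1.1e-07,3.8e-07
318,24,851,8.6e-06,0.074424366,1.3e-07,4.3e-07
318,27,872,1.242e-05,0.11013539,4.1e-07,9.6e-07
328,12,509,1.1e-06,0.0056936969,4e-08,9e-08
328,15,656,2.1e-06,0.01400901,4e-08,1.2e-07
328,18,725,2.81e-06,0.020717099,1.3e-07,3e-07
328,21,769,8.4e-06,0.065689004,1.9e-07,5.3e-07
328,24,802,9.72e-06,0.07927354,2.1e-07,5.9e-07
328,27,829,1.468e-05,0.12375717,3.2e-07,9.1e-07
338,12,388,8.1e-07,0.0031959538,3e-08,7e-08
338,15,557,1.37e-06,0.0077599649,2e-08,7e-08
338,18,652,2.11e-06,0.013989892,3e-08,1.1e-07
338,21,710,9.81e-06,0.070829637,4.1e-07,9.3e-07
338,24,751,1.197e-05,0.091416099,1.1e-07,5.7e-07
338,27,783,2.027e-05,0.16140155,9.1e-07,2.02e-06
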