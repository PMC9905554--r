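temperature_K,pressure_MPa,reported_S_g_L
308,12,0.0305
308,15,0.0415
308,18,0.0475
308,21,0.0557
308,24,0.0635
308,27,0.0849
318,12,0.0148
318,15,0.0264
318,18,0.0337
318,21,0.0618
318,24,0.0743
318,27,0.1101
328,12,0.0057
328,15,0.014
328,18,0.0206
328,21,0.0656
328,24,0.0792
328,27,0.1235
338,12,0.0031
338,15,0.0078
338,18,0.0139
338,21,0.0708
338,24,0.0914
338,27,0.1613
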