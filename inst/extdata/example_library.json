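{"frequency_mhz":600,"internal_standard":{"name":"DSS","role":"target","reporter_center_ppm":0.0001,"window_halfwidth_ppm":0.006,"unit_response":12,"components":[{"center_ppm":0.0001,"rel_height":12,"fwhm_hz":1.2}],"known_concentration_mM":0.29},"entries":{"met_01":{"name":"met_01","role":"target","reporter_center_ppm":3.1463,"window_halfwidth_ppm":0.004,"unit_response":1.33455830563325,"components":[{"center_ppm":3.1463,"rel_height":1.33455830563325,"fwhm_hz":1.29154835524969}]},"met_02":{"name":"met_02","role":"target","reporter_center_ppm":6.0561,"window_halfwidth_ppm":0.004,"unit_response":1.12970733897979,"components":[{"center_ppm":6.0437,"rel_height":0.372021180096393,"fwhm_hz":1.3880029045511},{"center_ppm":6.0561,"rel_height":1.11606354028918,"fwhm_hz":1.3880029045511},{"center_ppm":6.0685,"rel_height":1.11606354028918,"fwhm_hz":1.3880029045511},{"center_ppm":6.0809,"rel_height":0.372021180096393,"fwhm_hz":1.3880029045511}]},"met_03":{"name":"met_03","role":"target","reporter_center_ppm":6.8335,"window_halfwidth_ppm":0.004,"unit_response":1.1383853251819,"components":[{"center_ppm":6.8203,"rel_height":0.375832457801638,"fwhm_hz":1.31206654924899},{"center_ppm":6.8335,"rel_height":1.12749737340491,"fwhm_hz":1.31206654924899},{"center_ppm":6.8467,"rel_height":1.12749737340491,"fwhm_hz":1.31206654924899},{"center_ppm":6.8599,"rel_height":0.375832457801638,"fwhm_hz":1.31206654924899}]},"met_04":{"name":"met_04","role":"target","reporter_center_ppm":7.6097,"window_halfwidth_ppm":0.004,"unit_response":1.60251466871707,"components":[{"center_ppm":7.5967,"rel_height":0.795001278014388,"fwhm_hz":1.38933364651166},{"center_ppm":7.6097,"rel_height":1.59000255602878,"fwhm_hz":1.38933364651166},{"center_ppm":7.6227,"rel_height":0.795001278014388,"fwhm_hz":1.38933364651166}]},"met_05":{"name":"met_05","role":"target","reporter_center_ppm":8.2963,"window_halfwidth_ppm":0.004,"unit_response":1.06939756343296,"components":[{"center_ppm":8.2861,"rel_height":0.350394373464708,"fwhm_hz":1.38114762618206},{"center_ppm":8.2963,"rel_height":1.05118312039413,"fwhm_hz":1.38114762618206},{"center_ppm":8.3067,"rel_height":1.05118312039413,"fwhm_hz":1.38114762618206},{"center_ppm":8.3169,"rel_height":0.350394373464708,"fwhm_hz":1.38114762618206}]},"met_06":{"name":"met_06","role":"target","reporter_center_ppm":8.4841,"window_halfwidth_ppm":0.004,"unit_response":1.38279465561021,"components":[{"center_ppm":8.4611,"rel_height":0.227306009332339,"fwhm_hz":1.36221102825366},{"center_ppm":8.4727,"rel_height":0.909224037329356,"fwhm_hz":1.36221102825366},{"center_ppm":8.4841,"rel_height":1.36383605599403,"fwhm_hz":1.36221102825366},{"center_ppm":8.4955,"rel_height":0.909224037329356,"fwhm_hz":1.36221102825366},{"center_ppm":8.5071,"rel_height":0.227306009332339,"fwhm_hz":1.36221102825366}]},"unknown_1":{"name":"unknown_1","role":"interferent","reporter_center_ppm":0.9457,"window_halfwidth_ppm":0.005,"unit_response":0.916652756463736,"components":[{"center_ppm":0.9457,"rel_height":0.916652756463736,"fwhm_hz":1.20078966775909}]},"unknown_2":{"name":"unknown_2","role":"interferent","reporter_center_ppm":0.9627,"window_halfwidth_ppm":0.005,"unit_response":0.306600732193328,"components":[{"center_ppm":0.9627,"rel_height":0.306600732193328,"fwhm_hz":1.2415317945648}]}}}
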