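chromophore,tissue,wavelength_nm,mu_a_per_m
water,gray_matter,630,0.26
water,gray_matter,700,0.5
water,gray_matter,810,1.66
water,white_matter,630,0.23
water,white_matter,700,0.43
water,white_matter,810,1.45
fat,gray_matter,630,0.04
fat,gray_matter,700,0.03
fat,gray_matter,810,0.05
fat,white_matter,630,0.08
fat,white_matter,700,0.06
fat,white_matter,810,0.1
oxyhemoglobin,gray_matter,630,14.06
oxyhemoglobin,gray_matter,700,12.17
oxyhemoglobin,gray_matter,810,22.44
oxyhemoglobin,white_matter,630,3.37
oxyhemoglobin,white_matter,700,2.92
oxyhemoglobin,white_matter,810,5.38
deoxyhemoglobin,gray_matter,630,73
deoxyhemoglobin,gray_matter,700,34.2
deoxyhemoglobin,gray_matter,810,15.48
deoxyhemoglobin,white_matter,630,59.92
deoxyhemoglobin,white_matter,700,28.11
deoxyhemoglobin,white_matter,810,12.72
oxidized_cco,gray_matter,630,35.64
oxidized_cco,gray_matter,700,14.04
oxidized_cco,gray_matter,810,16.2
oxidized_cco,white_matter,630,2.34
oxidized_cco,white_matter,700,0.9
oxidized_cco,white_matter,810,1.1
reduced_cco,gray_matter,630,4.25
reduced_cco,gray_matter,700,1.97
reduced_cco,gray_matter,810,1.26
reduced_cco,white_matter,630,0.13
reduced_cco,white_matter,700,0.06
reduced_cco,white_matter,810,0.04
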